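# OGDscan

Genome scans for **outliers of genetic differentiation (OGDs)** and
selective sweeps in structured conspecific populations, from biallelic SNV
genotypes.

When divergent natural selection restricts gene flow at particular loci,
those loci stand out simultaneously in *relative* divergence
(Weir–Cockerham F<sub>ST</sub>) and *absolute* divergence (d<sub>XY</sub>),
and often carry the footprint of a selective sweep — locally depressed
diversity and a skewed site frequency spectrum.  OGDscan packages that
whole inferential chain for population geneticists:

1. **Windowed statistics** — Weir–Cockerham θ (1984 variance components,
   ratio of sums), frequency-based d<sub>XY</sub> and nucleotide diversity
   π in tiling windows (500 kb for F<sub>ST</sub>/d<sub>XY</sub>, 100 kb
   for π, aggregated by length-weighted mean), plus Kendall τ between
   d<sub>XY</sub> and mean π.
2. **Sweep scan** — a SweepFinder/SweeD-family composite likelihood ratio
   CLR(x) = 2(max<sub>α</sub> log L − log L<sub>0</sub>) on a grid of 1000
   positions per chromosome, built on the folded SFS with the
   star-genealogy escape model p<sub>e</sub> = 1 − e<sup>−αd</sup>.
3. **Outlier calling** — top 2% windows per statistic, OGD = intersection;
   sweep loci as runs of ≥2 consecutive grid points in the top 0.05% of
   CLR values.
4. **Permutation tests** — genome-wide F<sub>ST</sub> significance by label
   shuffling; OGD × sweep-target window association against a uniform
   resampling null (checked against the exact hypergeometric tail).
5. **Enrichment** — one-tailed Fisher tests for gene families (e.g. CYP,
   MDR) and GO terms inside sweep-targeted OGDs, with BH FDR < 0.1.
6. **Synthetic data** — a Balding–Nichols generator with planted sweeps
   and annotated gene tables, so the full pipeline is testable end to end.

Inputs are standard: a VCF of biallelic SNVs, a two-column sample→population
map, and a tab-separated gene table; all outputs are tab-separated tables
with BED-style 0-based half-open window coordinates.

## Worked example

```r
library(OGDscan)

# the reference synthetic scenario: 3 populations (SA 10, ML 10, EGT 11
# diploids), 12 x 2 Mb chromosomes, ~2500 SNVs each, one divergent sweep
# in SA on chr3 at 1.25 Mb, CYP-family enrichment x20 in the swept region
report <- runPipeline(runConfig(seed = 11))

print(report$counts$genome_fst, digits = 4)
#>  EGT-ML  EGT-SA   ML-SA
#> 0.05304 0.04084 0.03555                # pairwise genome-wide WC theta

report$counts$fst_perm_p
#>     EGT-ML     EGT-SA      ML-SA
#> 0.00990099 0.00990099 0.00990099       # observed theta beat all 100 shuffles

report$counts$ogd
#> EGT-ML EGT-SA  ML-SA
#>      0      1      1                   # the chr3 sweep window is an OGD

report$counts$association_p[["SA"]]
#> 0.02197802                             # OGD x sweep overlap, 1000 permutations

print(report$enrichment$SA$family, digits = 4)
#>   label  a  b  c    d odds_ratio         p         q
#> 1   CYP 10 33 62 1895      9.262 1.439e-06 1.439e-06
#> 2   MDR  1 42 28 1929      1.640 4.700e-01 4.700e-01
```

Reading the output: the three genome-wide θ values sit in the 0.03–0.06
band the scenario plants; each is permutation-significant at the 100-replicate
floor (p = 1/101).  The window containing the planted sweep is called as an
OGD, the sweep scan's top-0.05% grid points form a locus overlapping it,
the OGD × sweep association is significant (p ≈ 0.022), and the CYP family
(10 of the 43 genes in the targeted window, against 62 of 1957 elsewhere)
is strongly overrepresented — the GO stage likewise returns the family's
dedicated "iron ion binding"-style term.

A command-line front end with `simulate`, `filter`, `stats`, `scan`,
`pca` and `run-all` subcommands is installed at
`system.file("scripts", "ogdscan.R", package = "OGDscan")`.

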