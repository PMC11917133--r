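---
title: "OGDscan: models and methods"
author: "OGDscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OGDscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

OGDscan implements an intraspecific divergence genome scan: from biallelic
SNV genotypes of several populations it computes windowed differentiation
and diversity statistics, scans each population for selective sweeps with a
composite likelihood ratio, calls rank-based outliers — including *OGDs*,
windows that are simultaneously extreme for relative and absolute
divergence — and asks, by permutation, whether the OGDs coincide with sweep
targets and whether particular gene families are overrepresented there.
This vignette records the models, the defaults and the design decisions.

## Windowed statistics

The pipeline starts from a `VariantTable`: biallelic SNVs with diploid
genotype codes 0/1/2 (`NA` for missing), hard-filtered on the usual
GATK-style annotations (`QD < 2`, `FS > 60`, `MQ < 40`, `MQRankSum <
-12.5`, `ReadPosRankSum < -8`; a missing annotation cannot fire its
criterion) and, by default, restricted to sites without any missing
genotype — both switches are exposed in the run config, because full-call
restriction trades sites for uniform sample size.

Chromosomes are tiled into non-overlapping windows — 500 kb for
$F_{ST}$/$d_{XY}$, 100 kb natively for $\pi$, with the final partial window
kept and flagged.  Within-population diversity per site is the unbiased
pairwise heterozygosity $2j(n-j)/(n(n-1))$ for $j$ alternate alleles among
$n$ called chromosomes; window $\pi$ divides the site sum by the window
length in bp, so monomorphic stretches dilute diversity and a window with
no variants reports 0.  Absolute divergence is frequency-based,
$d_{XY} = L^{-1}\sum_i [p_A(1-p_B) + p_B(1-p_A)]$, equivalent to the mean
difference over between-population haplotype pairs under unphased diploids;
windows without contributing variants report `NA` rather than a fabricated
0, since absence of variants is informative for diversity but not for a
divergence ratio.  The 100-kb $\pi$ windows aggregate exactly into the
500-kb windows by length-weighted mean, which is also how the $d_{XY}$
versus mean-$\pi$ comparison (summarized by Kendall's $\tau_b$) is built.

Differentiation uses the Weir–Cockerham (1984) variance-components
estimator for two populations with observed heterozygote counts: per-site
components $a$ (among populations), $b$ (among individuals within), $c$
(within individuals), combined as a ratio of sums
$\hat\theta = \sum a / \sum(a+b+c)$ over contributing sites (at least two
called diploids per population; sites with $a+b+c=0$ excluded).  Per-site
sample sizes are the called chromosome counts, so missing data are handled
the way vcftools handles them.

## The sweep scan

Sweep detection is a SweepFinder/SweeD-family composite likelihood ratio
on a grid of positions per chromosome (default 1000), using the folded
site frequency spectrum so that no ancestral polarization is needed.  The
background spectrum is the genome-wide empirical folded SFS of the scanned
population, with missing-data sites down-projected hypergeometrically to
the smallest common chromosome count and the projected monomorphic mass
discarded.

The sweep model is the standard star-genealogy escape parameterization: a
lineage sampled at distance $d$ from a sweep of intensity $\alpha$ (per
bp) escapes with probability $p_e = 1 - e^{-\alpha d}$.  At a site whose
background frequency class is $j$ of $n$ (the folded spectrum is unfolded
symmetrically), $E \sim \mathrm{Binomial}(n, p_e)$ lineages escape and
carry the derived allele independently with probability $j/n$, while the
$n-E$ swept lineages form a single block that is derived all-or-none with
the same probability.  Folding the resulting count distribution, dropping
the monomorphic classes and renormalizing gives the per-site likelihood
$P(k \mid \alpha, d)$; the neutral likelihood is the background spectrum
itself.  At each grid position the scan sums log-likelihoods over the
polymorphic sites within 1 Mb, maximizes over a log-spaced grid of 24
intensities spanning $10^{-8}$–$10^{-1}$ per bp *plus the neutral model*,
and reports $\mathrm{CLR} = 2(\max_\alpha \log L - \log L_0) \ge 0$
together with the maximizing $\hat\alpha$.

Numerical choices: site distances are floored at 1 bp because $p_e = 0$
makes the polymorphism-conditioned distribution undefined; the per-site
distribution is evaluated through a precomputed 160-row lookup table over
$\log(\alpha d)$ (the exact function is exported as `sweepSiteProbs()` and
is what the tests enumerate against); the per-chromosome inner loop is
compiled code, as is usual for this family of scans.  Only sites whose
called chromosome count equals the spectrum's sample size enter the scan;
the projection handles missing data for the *spectrum*, not for individual
site likelihoods.

Because the likelihood is conditioned on polymorphism (VCF input carries
no invariant sites — a deliberate divergence from invariant-site-inclusive
SweepFinder likelihoods), absolute CLR values are shifted relative to such
implementations and, notably, CLR at the center *decreases* for very hard
sweeps: a sweep with $1/\alpha$ much smaller than the inter-SNV spacing
erases the polymorphic sites that carry its own signal.  Rank-based
outlier calling and localization are unaffected in the regimes the
reference scenario uses, and the property tests assert the direction the
conditioned model actually implies.

## Outliers, OGDs and permutation tests

All outlier calls are rank-based, per the scan's thresholds: top 2% of
windows for $F_{ST}$ and for $d_{XY}$ per population pair (ties at the cut
included, `NA` excluded before ranking), OGDs as their intersection.  CLR
outliers are the top 0.05% of grid points genome-wide per population; a
sweep *locus* requires at least two consecutive above-threshold grid
points, and loci are projected onto the window universe by half-open
interval overlap (grid points padded by half a grid step).

Two permutation tests mirror the scan's inferential questions.
Genome-wide $F_{ST}$ significance shuffles sample labels between the two
populations (group sizes preserved, 100 replicates by default) and
recomputes $\hat\theta$.  The OGD-sweep association counts windows that
are both OGD and sweep target, then redraws the sweep-target set uniformly
without replacement from the universe (1000 replicates by default); a
circular-rotation null that preserves adjacency is available as an option.
Both report the +1-corrected one-sided estimate
$p = (1 + \#\{null \ge obs\})/(reps + 1)$, which can never be exactly
zero — under the exchangeable null the association p converges to the
hypergeometric upper tail, which is how the tests check it.  The
association universe is the set of windows with defined $F_{ST}$ in both
pairs involving the focal population, and that population's OGD set is the
union over its pairs.

## Enrichment

Genes overlap target regions by half-open interval intersection and are
counted once regardless of how many windows they touch.  Family
overrepresentation in the sweep-targeted OGDs is a one-tailed (greater)
Fisher exact test over the universe of all annotated genes; GO terms are
tested the same way — only terms carried by at least one target gene, to
avoid inflating the correction — with Benjamini–Hochberg control at
FDR < 0.1.  GO terms are flat labels; no GO-graph propagation.

## The synthetic scenario

The generator exists so that every stage is testable without external
data; it produces the statistical structure the scan assumes, not
realistic genomes.  Genotypes follow the Balding–Nichols model: ancestral
frequency $p \sim U(0.05, 0.95)$ per site, population frequency
$p_k \sim \mathrm{Beta}(p(1-F_k)/F_k,\ (1-p)(1-F_k)/F_k)$, genotypes
$\mathrm{Binomial}(2, p_k)$.  This gives a closed-form differentiation
target — pairwise $\hat\theta \approx (F_a + F_b)/2$ — so estimator
recovery is a well-posed test.  The reference scenario uses three
populations (SA, ML, EGT) of 10, 10 and 11 diploids with
$F = (0.010, 0.049, 0.058)$, chosen so the three pairwise estimates land
near 0.034, 0.053 and 0.029, i.e. genome-wide differentiation in the
0.03–0.06 range typical of structured conspecific populations.  The
genome is scaled for desk-size computation: 12 chromosomes of 2 Mb with
about 2500 SNVs each (positions uniform, deduplicated), which keeps a full
pipeline run around a minute while leaving 48 windows at the default
500-kb size — enough for rank-based calling to be non-trivial.

Sweeps are injected through the *same* star-genealogy model the scan
fits (generative–inferential duality), using each site's observed
population frequency as its class: localization tests then measure
estimator correctness, not model misspecification.  The default planted
sweep sits mid-window (chr3 at 1.25 Mb) with $\alpha = 10^{-5}$ per bp, a
footprint of $1/\alpha = 100$ kb that spans many grid steps, so the
top-0.05% points form consecutive runs callable by the two-consecutive
rule.  One deliberate extension: in *divergent* mode the swept block
carries the locally rarer allele.  With unlinked sites, frequency-weighted
fixation leaves the expected $d_{XY}$ unchanged, so a planted sweep would
never be a $d_{XY}$ outlier and OGDs could not form; fixing the minor
allele emulates divergent selection favoring a novel allele, elevating
both $F_{ST}$ and $d_{XY}$ at the locus while leaving the folded spectrum
the scan sees essentially unchanged.  Gene annotations place genes
uniformly, multiply the focal family's probability (default CYP, factor
20) inside sweep regions, and give that family a dedicated GO term so the
enrichment stage has a recoverable signal.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps (sites are unlinked; none of the implemented statistics
model LD), demography, mutation-rate variation, sequencing error or
genotype uncertainty.  Passing tests therefore demonstrate estimator and
pipeline correctness under the stated models — not robustness to the
violations real resequencing data bring.

## Determinism and problem sizes

A single run seed fans out to per-stage seeds through a deterministic
splitter, so stages are reproducible independently of execution order and
a full run is bit-reproducible.  The test suite and the acceptance script
use the reference scenario above plus smaller fixtures: estimator oracles
on ≤100-site tables, parameter recovery at 20,000 sites and 2 × 20
diploids, sweep localization over seeded replicates of a 4 × 2-Mb genome,
and association-null checks against the exact hypergeometric tail.  These
sizes are the package's own choices for a desk-scale, fully reproducible
validation of the method.

## Known limitations

* The polymorphism-conditioned CLR is not comparable in absolute value to
  invariant-site-inclusive implementations; use ranks.
* Two-population $F_{ST}$ only; multi-population $\theta$ over more than
  two groups is out of scope (pairs are scanned separately).
* The PCA quick-look mean-imputes missing genotypes, which shrinks
  structure when missingness correlates with population.
* With very few windows the top-2% rule selects a single window; OGD
  calling then hinges on one rank in each statistic.
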