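# Synthetic structured-population data: Balding-Nichols genotypes, planted
# sweeps, and annotated gene tables.

#' Simulation scenario
#'
#' Describes a structured-population dataset: population sizes, a
#' Balding-Nichols differentiation parameter `F` per population, a scaled
#' genome, planted sweeps and a gene-family enrichment inside the swept
#' regions.  Defaults describe the package's reference scenario: three
#' populations (SA, ML, EGT) of 10, 10 and 11 diploids with per-population
#' `F` of 0.010, 0.049 and 0.058 (chosen so the three pairwise
#' Weir-Cockerham estimates land near 0.034, 0.053 and 0.029 via the
#' additive approximation \eqn{\theta_{ab} \approx (F_a + F_b)/2}), a
#' 12 x 2 Mb genome with ~2500 SNVs per chromosome, and one divergent sweep
#' in SA on chr3 whose region is enriched 20-fold for the CYP family.
#'
#' @slot popNames population labels.
#' @slot diploids diploid sample count per population.
#' @slot nChrom number of chromosomes.
#' @slot chromLength chromosome length in bp.
#' @slot nSites target SNV count per chromosome (duplicated uniform draws
#'   are removed, so the realized count can be slightly lower).
#' @slot F Balding-Nichols differentiation per population, in (0, 1).
#' @slot sweeps list of sweeps, each a list with elements `pop`, `chrom`,
#'   `center` (bp), `alpha` (per bp) and optional `divergent` flag.
#' @slot regionHalfWidth half-width in bp of the annotated sweep region
#'   around each sweep center.
#' @slot nGenes number of genes to simulate.
#' @slot familyProbs baseline gene-family probabilities (named, sums to 1).
#' @slot focalFamily family whose probability is multiplied by
#'   `enrichFactor` inside sweep regions.
#' @slot enrichFactor enrichment factor (>= 1).
#' @slot focalGO dedicated GO term carried by every focal-family gene.
#' @slot seed RNG seed; fixed seed gives bit-reproducible output.
#' @export
setClass("SimScenario", representation(
    popNames = "character", diploids = "integer", nChrom = "integer",
    chromLength = "numeric", nSites = "integer", F = "numeric",
    sweeps = "list", regionHalfWidth = "numeric", nGenes = "integer",
    familyProbs = "numeric", focalFamily = "character",
    enrichFactor = "numeric", focalGO = "character", seed = "integer"))

setValidity("SimScenario", function(object) {
    msg <- character()
    np <- length(object@popNames)
    if (length(object@diploids) != np || length(object@F) != np)
        msg <- c(msg, "diploids and F must match popNames in length")
    if (any(object@diploids < 1)) msg <- c(msg, "diploids must be positive")
    if (any(object@F <= 0) || any(object@F >= 1))
        msg <- c(msg, "F must lie strictly in (0, 1)")
    if (object@nChrom < 1 || object@chromLength < 1 || object@nSites < 1)
        msg <- c(msg, "genome dimensions must be positive")
    if (object@enrichFactor < 1) msg <- c(msg, "enrichFactor must be >= 1")
    for (sw in object@sweeps) {
        if (!all(c("pop", "chrom", "center", "alpha") %in% names(sw)))
            msg <- c(msg, "each sweep needs pop, chrom, center, alpha")
        else {
            if (!(sw$pop %in% object@popNames))
                msg <- c(msg, paste("sweep population unknown:", sw$pop))
            if (sw$center < 0 || sw$center > object@chromLength)
                msg <- c(msg, "sweep center outside chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SimScenario-class Constructor with reference-scenario
#'   defaults.
#' @param popNames,diploids,nChrom,chromLength,nSites,F,sweeps see slots.
#' @param regionHalfWidth,nGenes,familyProbs,focalFamily see slots.
#' @param enrichFactor,focalGO,seed see slots.
#' @export
simScenario <- function(popNames = c("SA", "ML", "EGT"),
                        diploids = c(10L, 10L, 11L),
                        nChrom = 12L, chromLength = 2e6, nSites = 2500L,
                        F = c(0.010, 0.049, 0.058),
                        sweeps = list(list(pop = "SA", chrom = "chr3",
                                           center = 1.25e6, alpha = 1e-5,
                                           divergent = TRUE)),
                        regionHalfWidth = 150000, nGenes = 2000L,
                        familyProbs = c(CYP = 0.03, MDR = 0.02, other = 0.95),
                        focalFamily = "CYP", enrichFactor = 20,
                        focalGO = "GO:0005506", seed = 1L) {
    new("SimScenario", popNames = popNames,
        diploids = as.integer(diploids), nChrom = as.integer(nChrom),
        chromLength = chromLength, nSites = as.integer(nSites), F = F,
        sweeps = sweeps, regionHalfWidth = regionHalfWidth,
        nGenes = as.integer(nGenes), familyProbs = familyProbs,
        focalFamily = focalFamily, enrichFactor = enrichFactor,
        focalGO = focalGO, seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
    cat("SimScenario:", length(object@popNames), "populations (",
        paste(object@popNames, object@diploids, sep = "x", collapse = ", "),
        "diploids ),", object@nChrom, "x",
        format(object@chromLength / 1e6), "Mb chromosomes,",
        object@nSites, "sites each\n")
    cat("  F =", paste(format(object@F), collapse = ", "),
        "; sweeps:", length(object@sweeps),
        "; seed =", object@seed, "\n")
    invisible(object)
})

#' Annotated sweep regions of a scenario
#'
#' @param scn a [SimScenario-class].
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `pop`;
#'   zero rows when the scenario plants no sweep.
#' @export
sweepRegions <- function(scn) {
    if (!length(scn@sweeps))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), pop = character()))
    do.call(rbind, lapply(scn@sweeps, function(sw) data.frame(
        chrom = sw$chrom,
        start = max(0, sw$center - scn@regionHalfWidth),
        end = min(scn@chromLength, sw$center + scn@regionHalfWidth),
        pop = sw$pop, stringsAsFactors = FALSE)))
}

#' Simulate structured-population genotypes (Balding-Nichols)
#'
#' Per site an ancestral frequency `p ~ Uniform(0.05, 0.95)` is drawn; each
#' population's frequency comes from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `F p (1-p)`), and
#' diploid genotypes are `Binomial(2, p_k)`.  Site positions are uniform
#' draws, sorted and deduplicated.  Sites are unlinked.
#'
#' @param scn a [SimScenario-class] (sweeps in the scenario are *not*
#'   applied here; see [injectSweep()] and [simulateDataset()]).
#' @return list with elements `vt` (a [VariantTable-class] with population
#'   labels in `colData`), `pm` (named population map) and `ci` (contig
#'   lengths).
#' @export
simulateGenotypes <- function(scn) {
    set.seed(scn@seed)
    np <- length(scn@popNames)
    nDip <- scn@diploids
    samples <- unlist(lapply(seq_len(np), function(k)
        sprintf("%s_%02d", scn@popNames[k], seq_len(nDip[k]))))
    pm <- stats::setNames(rep(scn@popNames, nDip), samples)
    ci <- stats::setNames(rep(scn@chromLength, scn@nChrom),
                          paste0("chr", seq_len(scn@nChrom)))
    chromL <- list()
    posL <- list()
    genoL <- list()
    for (ch in names(ci)) {
        pos <- sort(unique(sample.int(scn@chromLength, scn@nSites,
                                      replace = TRUE)))
        ns <- length(pos)
        p <- stats::runif(ns, 0.05, 0.95)
        g <- matrix(0L, ns, sum(nDip))
        col0 <- 0L
        for (k in seq_len(np)) {
            Fk <- scn@F[k]
            pk <- stats::rbeta(ns, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
            for (d in seq_len(nDip[k]))
                g[, col0 + d] <- stats::rbinom(ns, 2L, pk)
            col0 <- col0 + nDip[k]
        }
        chromL[[ch]] <- rep(ch, ns)
        posL[[ch]] <- pos
        genoL[[ch]] <- g
    }
    geno <- do.call(rbind, genoL)
    colnames(geno) <- samples
    vt <- VariantTable(chrom = unlist(chromL), pos = unlist(posL),
                       ref = rep("A", nrow(geno)), alt = rep("T", nrow(geno)),
                       geno = geno, seqlengths = ci, population = pm)
    list(vt = vt, pm = pm, ci = ci)
}

#' Inject a selective sweep into one population
#'
#' Re-draws the target population's allele counts at every site on the
#' sweep chromosome from the star-genealogy sweep model (the generative
#' twin of the scan's [sweepSiteProbs()] likelihood): a lineage at distance
#' `d` escapes with probability [escapeProb()]`(alpha, d)`; escapees carry
#' the alternate allele independently with the site's current population
#' frequency; the non-escaped lineages form one block carrying a single
#' allele.  New allele counts are converted to diploid genotypes by random
#' assortment.  Other populations are untouched.
#'
#' In the default (frequency-weighted) mode the block allele is alternate
#' with the current frequency, matching the inference model exactly.  With
#' `divergent = TRUE` the block carries the locally *rarer* allele
#' (probability `1 - p` of being alternate), emulating divergent selection
#' favoring a novel allele: this elevates \eqn{F_{ST}} and \eqn{d_{XY}} at
#' the locus while leaving the folded spectrum seen by the scan essentially
#' unchanged.
#'
#' @param vt a [VariantTable-class].
#' @param pm population map; defaults to `colData(vt)$population`.
#' @param pop target population label.
#' @param chrom sweep chromosome.
#' @param center sweep center in bp.
#' @param alpha sweep intensity per bp.
#' @param divergent logical; see Details.
#' @param seed optional RNG seed (otherwise continues the current stream).
#' @return the modified [VariantTable-class].
#' @export
injectSweep <- function(vt, pm = NULL, pop, chrom, center, alpha,
                        divergent = FALSE, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    idx <- .popIndex(vt, pm, pop)
    rr <- SummarizedExperiment::rowRanges(vt)
    onChrom <- which(as.character(GenomicRanges::seqnames(rr)) == chrom)
    if (!length(onChrom)) stop("no sites on chromosome ", chrom)
    g <- genotypes(vt)
    pos <- GenomicRanges::start(rr)[onChrom]
    pe <- escapeProb(alpha, abs(pos - center))
    for (ii in seq_along(onChrom)) {
        row <- onChrom[ii]
        gi <- g[row, idx]
        called <- which(!is.na(gi))
        nd <- length(called)
        if (nd == 0L) next
        n <- 2L * nd
        p <- sum(gi[called]) / n
        E <- stats::rbinom(1L, n, pe[ii])
        kEsc <- stats::rbinom(1L, E, p)
        blockP <- if (divergent) 1 - p else p
        block <- if (E < n) stats::rbinom(1L, 1L, blockP) else 0L
        k <- kEsc + block * (n - E)
        newg <- integer(nd)
        if (k > 0L) {
            slots <- sample.int(n, k)
            newg <- tabulate(ceiling(slots / 2), nbins = nd)
        }
        gi[called] <- as.integer(newg)
        g[row, idx] <- gi
    }
    SummarizedExperiment::assay(vt, "GT") <- g
    vt
}

#' Simulate an annotated gene table
#'
#' Genes are placed uniformly along the genome (chromosome chosen
#' proportionally to length).  Inside the supplied sweep regions the
#' probability of the focal family label is multiplied by `enrichFactor`
#' and the family distribution renormalized.  Every focal-family gene
#' carries a dedicated GO term (`focalGO`); every other named family gets
#' its own term, and background genes draw 0-2 generic terms.
#'
#' @param ci named contig lengths (bp).
#' @param regions sweep regions: data.frame `chrom`, `start`, `end`
#'   (0-based half-open); zero rows for none.
#' @param nGenes number of genes.
#' @param familyProbs named baseline family probabilities.
#' @param enrichFactor multiplier (>= 1) for `focalFamily` inside regions.
#' @param focalFamily focal family label.
#' @param focalGO dedicated GO term of the focal family.
#' @param geneLength gene length in bp.
#' @param seed optional RNG seed.
#' @return gene table data.frame (see [readGeneTable()]).
#' @export
simulateAnnotations <- function(ci, regions, nGenes = 2000,
                                familyProbs = c(CYP = 0.03, MDR = 0.02,
                                                other = 0.95),
                                enrichFactor = 20, focalFamily = "CYP",
                                focalGO = "GO:0005506", geneLength = 2000,
                                seed = NULL) {
    stopifnot(enrichFactor >= 1, abs(sum(familyProbs) - 1) < 1e-9)
    if (!is.null(seed)) set.seed(seed)
    chrom <- sample(names(ci), nGenes, replace = TRUE,
                    prob = as.numeric(ci) / sum(as.numeric(ci)))
    start <- floor(stats::runif(nGenes, 0, pmax(1, ci[chrom] - geneLength)))
    end <- start + geneLength
    inRegion <- logical(nGenes)
    if (nrow(regions)) {
        hits <- .halfOpenOverlaps(chrom, start, end,
                                  regions$chrom, regions$start, regions$end)
        inRegion[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    fams <- names(familyProbs)
    boosted <- familyProbs
    boosted[focalFamily] <- boosted[focalFamily] * enrichFactor
    boosted <- boosted / sum(boosted)
    family <- character(nGenes)
    family[!inRegion] <- sample(fams, sum(!inRegion), replace = TRUE,
                                prob = familyProbs)
    if (any(inRegion))
        family[inRegion] <- sample(fams, sum(inRegion), replace = TRUE,
                                   prob = boosted)
    genericPool <- sprintf("GO:GEN%04d", seq_len(30))
    go <- vapply(family, function(f) {
        if (f == focalFamily) return(focalGO)
        if (f != "other") return(paste0("GO:FAM:", f))
        k <- sample(0:2, 1)
        if (k == 0) "" else paste(sample(genericPool, k), collapse = ",")
    }, character(1))
    data.frame(gene_id = sprintf("gene%05d", seq_len(nGenes)),
               chrom = chrom, start = start, end = end,
               family = family, go = unname(go),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete annotated dataset
#'
#' Runs [simulateGenotypes()], applies every sweep in the scenario with
#' [injectSweep()], and generates the gene table with
#' [simulateAnnotations()], all under seeds derived deterministically from
#' the scenario seed.
#'
#' @param scn a [SimScenario-class].
#' @return list: `vt`, `pm`, `ci`, `genes`, `regions` (annotated sweep
#'   regions), `scenario`.
#' @export
simulateDataset <- function(scn) {
    sim <- simulateGenotypes(scn)
    vt <- sim$vt
    for (i in seq_along(scn@sweeps)) {
        sw <- scn@sweeps[[i]]
        vt <- injectSweep(vt, sim$pm, pop = sw$pop, chrom = sw$chrom,
                          center = sw$center, alpha = sw$alpha,
                          divergent = isTRUE(sw$divergent),
                          seed = .splitSeed(scn@seed, paste0("sweep", i)))
    }
    regions <- sweepRegions(scn)
    genes <- simulateAnnotations(sim$ci, regions, nGenes = scn@nGenes,
                                 familyProbs = scn@familyProbs,
                                 enrichFactor = scn@enrichFactor,
                                 focalFamily = scn@focalFamily,
                                 focalGO = scn@focalGO,
                                 seed = .splitSeed(scn@seed, "genes"))
    list(vt = vt, pm = sim$pm, ci = sim$ci, genes = genes,
         regions = regions, scenario = scn)
}
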