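#' VariantTable: biallelic SNV genotypes with genomic coordinates
#'
#' A `VariantTable` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one integer assay `"GT"` (sites x samples) of diploid genotype
#' codes counting alternate alleles: 0, 1, 2 or `NA` for missing.  Row ranges
#' are width-1 positions (1-based, as in VCF) whose `mcols` carry the `ref`
#' and `alt` allele symbols plus the numeric hard-filter annotations
#' `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum` (`NA` when absent from the
#' source VCF).  Contig lengths live in the `seqinfo`; a population label per
#' sample may live in `colData$population`.
#'
#' Sites are kept sorted by (contig, position) with no duplicate positions,
#' and every site is a biallelic SNV.  These invariants are enforced by the
#' validity method.
#'
#' @slot ... see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [readVCF()], [genotypes()], [contigIndex()]
#' @export
setClass("VariantTable", contains = "RangedSummarizedExperiment")

.validVariantTable <- function(object) {
    msg <- character()
    if (!("GT" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'GT' is required")
    else {
        g <- SummarizedExperiment::assay(object, "GT")
        if (!is.integer(g) && !all(is.na(g)))
            msg <- c(msg, "genotype codes must be integer")
        bad <- g[!is.na(g)]
        if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
            msg <- c(msg, "genotype codes must be in {0, 1, 2, NA}")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        if (any(GenomicRanges::width(rr) != 1L))
            msg <- c(msg, "row ranges must be width-1 positions")
        md <- GenomicRanges::mcols(rr)
        if (!all(c("ref", "alt") %in% colnames(md)))
            msg <- c(msg, "row mcols must contain 'ref' and 'alt'")
        else if (any(nchar(md$ref) != 1L) || any(nchar(md$alt) != 1L))
            msg <- c(msg, "all sites must be biallelic SNVs")
        key <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                      GenomicRanges::start(rr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (chrom, pos) sites")
        o <- order(as.integer(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("VariantTable", .validVariantTable)

.INFO_KEYS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Construct a VariantTable from vectors
#'
#' @param chrom character vector of contig names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character allele symbols per site.
#' @param geno integer matrix (sites x samples) of codes in `{0,1,2,NA}`.
#' @param info optional data.frame of numeric hard-filter annotations; missing
#'   keys among `QD, FS, MQ, MQRankSum, ReadPosRankSum` are filled with `NA`.
#' @param seqlengths named vector of contig lengths (bp); defaults to the
#'   largest observed position per contig.
#' @param population optional named population label per sample (stored in
#'   `colData$population`).
#' @return A [VariantTable-class] object, sorted by (chrom, pos).
#' @export
VariantTable <- function(chrom, pos, ref, alt, geno, info = NULL,
                         seqlengths = NULL, population = NULL) {
    geno <- as.matrix(geno)
    storage.mode(geno) <- "integer"
    stopifnot(length(chrom) == nrow(geno), length(pos) == nrow(geno))
    lev <- unique(as.character(chrom))
    if (!is.null(seqlengths)) {
        miss <- setdiff(lev, names(seqlengths))
        if (length(miss))
            stop("contigs absent from seqlengths: ", paste(miss, collapse = ", "))
        lev <- names(seqlengths)
        si <- GenomeInfoDb::Seqinfo(seqnames = lev,
                                    seqlengths = as.integer(seqlengths))
    } else {
        sl <- vapply(split(pos, factor(chrom, levels = lev)), max, numeric(1))
        si <- GenomeInfoDb::Seqinfo(seqnames = lev, seqlengths = as.integer(sl))
    }
    rr <- GenomicRanges::GRanges(factor(as.character(chrom), levels = lev),
                                 IRanges::IRanges(pos, width = 1L),
                                 seqinfo = si)
    md <- S4Vectors::DataFrame(ref = as.character(ref), alt = as.character(alt))
    for (k in .INFO_KEYS) {
        md[[k]] <- if (!is.null(info) && k %in% colnames(info))
            as.numeric(info[[k]]) else rep(NA_real_, length(rr))
    }
    GenomicRanges::mcols(rr) <- md
    cd <- S4Vectors::DataFrame(row.names = colnames(geno))
    if (!is.null(population)) {
        if (!is.null(names(population)) && !is.null(colnames(geno)))
            population <- population[colnames(geno)]
        cd$population <- as.character(population)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(GT = geno), rowRanges = rr, colData = cd)
    o <- order(as.integer(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    new("VariantTable", se[o, ])
}

#' @describeIn VariantTable Number of sites and samples.
#' @param object,vt a `VariantTable`.
#' @export
setMethod("show", "VariantTable", function(object) {
    g <- SummarizedExperiment::assay(object, "GT")
    cat("VariantTable:", nrow(object), "biallelic SNV sites x",
        ncol(object), "samples\n")
    cat("  contigs:", length(GenomeInfoDb::seqlengths(object)),
        sprintf("(%.1f Mb total)\n",
                sum(as.numeric(GenomeInfoDb::seqlengths(object))) / 1e6))
    cat(sprintf("  missing genotypes: %.2f%%\n",
                100 * mean(is.na(g))))
    if ("population" %in% colnames(SummarizedExperiment::colData(object))) {
        tb <- table(SummarizedExperiment::colData(object)$population)
        cat("  populations:",
            paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
    invisible(object)
})

#' Genotype matrix of a VariantTable
#' @param vt a [VariantTable-class].
#' @return integer matrix, sites x samples, codes in `{0,1,2,NA}`.
#' @export
genotypes <- function(vt) SummarizedExperiment::assay(vt, "GT")

#' Contig lengths of a VariantTable
#' @param vt a [VariantTable-class].
#' @return named numeric vector of contig lengths in bp.
#' @export
contigIndex <- function(vt) {
    sl <- GenomeInfoDb::seqlengths(vt)
    stats::setNames(as.numeric(sl), names(sl))
}

#' Population labels stored in a VariantTable
#' @param vt a [VariantTable-class].
#' @return named character vector (sample -> population), or `NULL`.
#' @export
populations <- function(vt) {
    cd <- SummarizedExperiment::colData(vt)
    if (!("population" %in% colnames(cd))) return(NULL)
    stats::setNames(as.character(cd$population), rownames(cd))
}

#' Folded site frequency spectrum
#'
#' Probability per folded minor-allele count class \eqn{m = 1, \ldots,
#' \lfloor n/2 \rfloor} for a sample of `n` chromosomes, conditioned on
#' polymorphism.
#'
#' @slot n sample size in chromosomes.
#' @slot probs numeric vector of class probabilities, summing to 1.
#' @seealso [backgroundSFS()], [sweepSiteProbs()]
#' @export
setClass("FoldedSFS", representation(n = "integer", probs = "numeric"))

setValidity("FoldedSFS", function(object) {
    msg <- character()
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (length(object@probs) != object@n %/% 2L)
        msg <- c(msg, "probs must have floor(n/2) classes")
    if (any(object@probs < 0)) msg <- c(msg, "probs must be non-negative")
    if (abs(sum(object@probs) - 1) > 1e-12)
        msg <- c(msg, "probs must sum to 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn FoldedSFS-class Constructor; `probs` is renormalized only if
#'   it already sums to 1 within 1e-12 (otherwise an error).
#' @param n sample size in chromosomes.
#' @param probs probability per folded class `1..floor(n/2)`.
#' @export
FoldedSFS <- function(n, probs) {
    new("FoldedSFS", n = as.integer(n), probs = as.numeric(probs))
}

setMethod("show", "FoldedSFS", function(object) {
    cat("FoldedSFS: n =", object@n, "chromosomes,",
        length(object@probs), "folded classes\n")
    cat("  singleton mass:", format(object@probs[1], digits = 4), "\n")
    invisible(object)
})

#' Composite-likelihood-ratio sweep scan results
#'
#' Per-chromosome grids of CLR values and fitted sweep intensities for one
#' population.  The underlying table has columns `chrom`, `pos` (bp, grid
#' positions), `clr` (composite likelihood ratio, >= 0) and `alphaHat`
#' (maximizing sweep intensity per bp; `NA` where the neutral model wins).
#'
#' @slot population population label scanned.
#' @slot table data.frame of grid results.
#' @slot params list of scan settings (alpha grid, max window, SFS size).
#' @seealso [clrScan()], [callSweepLoci()]
#' @export
setClass("SweepScan", representation(population = "character",
                                     table = "data.frame",
                                     params = "list"))

setValidity("SweepScan", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("chrom", "pos", "clr", "alphaHat")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
    else {
        if (any(tb$clr < -1e-9, na.rm = TRUE)) msg <- c(msg, "clr must be >= 0")
        byc <- split(tb$pos, tb$chrom)
        if (any(vapply(byc, function(p) any(diff(p) <= 0), logical(1))))
            msg <- c(msg, "grid positions must be strictly increasing per chromosome")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SweepScan", function(object) {
    tb <- object@table
    cat("SweepScan for population", object@population, "-",
        nrow(tb), "grid points on", length(unique(tb$chrom)), "chromosome(s)\n")
    if (nrow(tb))
        cat("  CLR: max", format(max(tb$clr), digits = 4),
            " median", format(stats::median(tb$clr), digits = 4), "\n")
    invisible(object)
})

#' Accessor for the grid table of a SweepScan
#' @param x a [SweepScan-class].
#' @return data.frame with columns `chrom`, `pos`, `clr`, `alphaHat`.
#' @export
scanTable <- function(x) x@table

#' Permutation test result
#'
#' @slot observed observed value of the test statistic.
#' @slot nullDraws statistic under the permutation null, one per replicate.
#' @slot p one-sided +1-corrected p value,
#'   \eqn{(1 + \#\{null \ge obs\}) / (reps + 1)}.
#' @slot seed RNG seed used.
#' @slot statistic short label of the statistic.
#' @export
setClass("PermutationResult",
         representation(observed = "numeric", nullDraws = "numeric",
                        p = "numeric", seed = "integer",
                        statistic = "character"))

setValidity("PermutationResult", function(object) {
    msg <- character()
    reps <- length(object@nullDraws)
    pexp <- (1 + sum(object@nullDraws >= object@observed)) / (reps + 1)
    if (abs(object@p - pexp) > 1e-12)
        msg <- c(msg, "p must equal (1 + #{null >= observed}) / (reps + 1)")
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult [", object@statistic, "]: observed =",
        format(object@observed, digits = 5),
        ", reps =", length(object@nullDraws),
        ", p =", format(object@p, digits = 4), "\n")
    invisible(object)
})

#' One-sided permutation p value
#' @param x a [PermutationResult-class].
#' @export
permPvalue <- function(x) x@p
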