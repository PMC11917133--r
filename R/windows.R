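# Windowed diversity and differentiation statistics.

#' Tile contigs into fixed-size windows
#'
#' Windows are non-overlapping consecutive intervals `[0,size)`,
#' `[size,2*size)`, ...; a final partial window is retained and flagged in
#' `mcols(.)$partial`.  Returned as a `GRanges` (1-based closed internally;
#' `.windowIds`/output files use the BED 0-based half-open convention).
#'
#' @param ci named vector of contig lengths in bp.
#' @param size window size in bp (default 500 kb).
#' @return `GRanges` of windows, named by their BED-style id.
#' @export
makeWindows <- function(ci, size = 500000) {
    stopifnot(size > 0, all(ci > 0))
    si <- GenomeInfoDb::Seqinfo(seqnames = names(ci),
                                seqlengths = as.integer(ci))
    w <- GenomicRanges::tileGenome(si,
                                   tilewidth = min(size, sum(as.numeric(ci))),
                                   cut.last.tile.in.chrom = TRUE)
    GenomicRanges::mcols(w)$partial <- GenomicRanges::width(w) < size
    names(w) <- .windowIds(w)
    w
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity \eqn{\pi = 2 j (n - j) / (n (n - 1))}
#' for `j` alternate alleles among `n` called chromosomes; the average
#' pairwise difference over all haplotype pairs.
#'
#' @param j alternate-allele count(s).
#' @param n called chromosome count(s); sites with `n < 2` return `NA`.
#' @return numeric vector of per-site \eqn{\pi}.
#' @export
sitePi <- function(j, n) {
    out <- 2 * j * (n - j) / (n * (n - 1))
    out[n < 2] <- NA_real_
    out
}

# Map sites to windows; returns integer window index per site (NA if none).
.siteWindow <- function(vt, windows) {
    hits <- IRanges::findOverlaps(SummarizedExperiment::rowRanges(vt), windows)
    idx <- rep(NA_integer_, nrow(vt))
    idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    idx
}

#' Windowed nucleotide diversity per population
#'
#' Window \eqn{\pi} is the sum of per-site \eqn{\pi} divided by the window
#' length in bp, so invariant stretches dilute diversity.  Windows without
#' variants report 0 (monomorphism is informative for diversity).
#'
#' @param vt a [VariantTable-class].
#' @param pm population map (sample -> label); defaults to
#'   `colData(vt)$population`.
#' @param windows `GRanges` from [makeWindows()]; defaults to 100-kb tiling.
#' @param size window size used when `windows` is NULL.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`, then one `pi_<pop>` column per population.
#' @export
windowPi <- function(vt, pm = NULL, windows = NULL, size = 100000) {
    pm <- .resolvePopMap(vt, pm)
    if (is.null(windows)) windows <- makeWindows(contigIndex(vt), size)
    wi <- .siteWindow(vt, windows)
    g <- genotypes(vt)
    nw <- length(windows)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
                      start = GenomicRanges::start(windows) - 1,
                      end = GenomicRanges::end(windows),
                      n_sites = as.integer(tabulate(wi, nbins = nw)),
                      stringsAsFactors = FALSE)
    L <- GenomicRanges::width(windows)
    for (pop in sort(unique(pm))) {
        sc <- .siteCounts(g, which(pm == pop))
        ps <- sitePi(sc$alt, sc$nChr)
        ok <- !is.na(ps) & !is.na(wi)
        acc <- rep(0, nw)
        if (any(ok)) {
            s <- rowsum(ps[ok], wi[ok])
            acc[as.integer(rownames(s))] <- s[, 1]
        }
        out[[paste0("pi_", pop)]] <- acc / L
    }
    rownames(out) <- names(windows)
    out
}

#' Windowed absolute divergence between two populations
#'
#' Per-bp \eqn{d_{XY}}: the mean, over between-population haplotype pairs,
#' of per-site differences, computed from allele frequencies as
#' \eqn{\sum_i [p_A(1-p_B) + p_B(1-p_A)] / L} with `L` the window length.
#' A site contributes only if both populations have at least one called
#' chromosome.  Windows with no contributing variant report `NA` (absence of
#' variants is informative for diversity, not for divergence ratios);
#' symmetric in the two populations by construction.
#'
#' @inheritParams windowPi
#' @param popA,popB population labels.
#' @return data.frame: window columns, `n_sites` (contributing sites) and
#'   `dxy`.
#' @export
windowDxy <- function(vt, pm = NULL, popA, popB, windows = NULL,
                      size = 500000) {
    pm <- .resolvePopMap(vt, pm)
    if (is.null(windows)) windows <- makeWindows(contigIndex(vt), size)
    wi <- .siteWindow(vt, windows)
    g <- genotypes(vt)
    a <- .siteCounts(g, which(pm == popA))
    b <- .siteCounts(g, which(pm == popB))
    ok <- a$nChr > 0 & b$nChr > 0 & !is.na(wi)
    pA <- a$alt / a$nChr
    pB <- b$alt / b$nChr
    d <- pA * (1 - pB) + pB * (1 - pA)
    nw <- length(windows)
    acc <- rep(0, nw)
    if (any(ok)) {
        s <- rowsum(d[ok], wi[ok])
        acc[as.integer(rownames(s))] <- s[, 1]
    }
    ns <- as.integer(tabulate(wi[ok], nbins = nw))
    data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
               start = GenomicRanges::start(windows) - 1,
               end = GenomicRanges::end(windows),
               n_sites = ns,
               dxy = ifelse(ns > 0, acc / GenomicRanges::width(windows),
                            NA_real_),
               row.names = names(windows), stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) per-site variance components for r = 2
# populations, from called-diploid counts, alt counts and heterozygote
# counts.  Returns a, b, c vectors; sites with < 2 called diploids in either
# population come back NA.
.wcComponents <- function(n1, alt1, het1, n2, alt2, het2) {
    r <- 2
    ok <- n1 >= 2 & n2 >= 2
    p1 <- alt1 / (2 * n1)
    p2 <- alt2 / (2 * n2)
    h1 <- het1 / n1
    h2 <- het2 / n2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a[!ok] <- NA_real_
    b[!ok] <- NA_real_
    cc[!ok] <- NA_real_
    list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST between two populations
#'
#' The 1984 variance-components estimator \eqn{\theta} for two populations,
#' using observed heterozygote counts (components a, b, c per site) and the
#' ratio-of-sums combination \eqn{\hat\theta = \sum a / \sum (a+b+c)} across
#' contributing sites.  Sites with fewer than two called diploids in either
#' population, or with \eqn{a+b+c = 0} (no variance), are excluded.
#'
#' @inheritParams windowDxy
#' @param windows `GRanges` of windows, or `NULL` for the genome-wide
#'   estimate.
#' @return if `windows` is `NULL`, a single numeric \eqn{\hat\theta};
#'   otherwise a data.frame with window columns, `n_sites` (contributing)
#'   and `fst` (`NA` where no site contributes), carrying the genome-wide
#'   estimate in `attr(., "genome")`.
#' @export
wcFst <- function(vt, pm = NULL, popA, popB, windows = NULL) {
    pm <- .resolvePopMap(vt, pm)
    g <- genotypes(vt)
    a <- .siteCounts(g, which(pm == popA))
    b <- .siteCounts(g, which(pm == popB))
    comp <- .wcComponents(a$nDip, a$alt, a$het, b$nDip, b$alt, b$het)
    tot <- comp$a + comp$b + comp$c
    use <- !is.na(tot) & tot > 0
    genome <- if (any(use)) sum(comp$a[use]) / sum(tot[use]) else NA_real_
    if (is.null(windows)) return(genome)
    wi <- .siteWindow(vt, windows)
    ok <- use & !is.na(wi)
    nw <- length(windows)
    sa <- rep(0, nw)
    st <- rep(0, nw)
    if (any(ok)) {
        m <- rowsum(cbind(comp$a[ok], tot[ok]), wi[ok])
        ii <- as.integer(rownames(m))
        sa[ii] <- m[, 1]
        st[ii] <- m[, 2]
    }
    ns <- as.integer(tabulate(wi[ok], nbins = nw))
    fst <- ifelse(ns > 0, sa / st, NA_real_)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
                      start = GenomicRanges::start(windows) - 1,
                      end = GenomicRanges::end(windows),
                      n_sites = ns, fst = fst,
                      row.names = names(windows), stringsAsFactors = FALSE)
    attr(out, "genome") <- genome
    out
}

#' Kendall rank correlation
#'
#' Tie-corrected \eqn{\tau_b} with an exact p value by enumeration for
#' \eqn{n \le 8} without ties and the normal approximation otherwise
#' (wrapping [stats::cor.test()]).  All-tied input returns `NA`.
#'
#' @param x,y numeric vectors of equal length (pairs with `NA` dropped).
#' @return list with elements `tau` and `p`.
#' @export
kendallTau <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 2) stop("need at least 2 complete pairs")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        return(list(tau = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "kendall",
                        exact = length(x) <= 8))
    list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Combined per-window divergence statistics for a population pair
#'
#' Computes Weir-Cockerham \eqn{F_{ST}} and \eqn{d_{XY}} in `windowSize`
#' windows and \eqn{\pi} natively in `piWindowSize` windows, aggregated to
#' the larger windows by length-weighted mean.
#'
#' @inheritParams windowDxy
#' @param windowSize F_ST / d_XY window size in bp (default 500 kb).
#' @param piWindowSize native \eqn{\pi} window size in bp (default 100 kb);
#'   must divide `windowSize` evenly for exact aggregation.
#' @return data.frame with one row per `windowSize` window: coordinates,
#'   `n_sites`, `fst`, `dxy`, `pi_<popA>`, `pi_<popB>`, `pi_mean`;
#'   genome-wide \eqn{\hat\theta} in `attr(., "genome_fst")` and the native
#'   \eqn{\pi} table in `attr(., "pi_table")`.
#' @export
windowStats <- function(vt, pm = NULL, popA, popB, windowSize = 500000,
                        piWindowSize = 100000) {
    pm <- .resolvePopMap(vt, pm)
    ci <- contigIndex(vt)
    big <- makeWindows(ci, windowSize)
    small <- makeWindows(ci, piWindowSize)
    fst <- wcFst(vt, pm, popA, popB, windows = big)
    dxy <- windowDxy(vt, pm, popA, popB, windows = big)
    pis <- windowPi(vt, pm, windows = small)
    # length-weighted aggregation of the small pi windows into the big ones
    parent <- .halfOpenOverlaps(pis$chrom, pis$start, pis$end,
                                fst$chrom, fst$start, fst$end)
    pw <- S4Vectors::subjectHits(parent)[order(S4Vectors::queryHits(parent))]
    wlen <- pis$end - pis$start
    agg <- function(v) {
        s <- rowsum(v * wlen, pw)
        l <- rowsum(wlen, pw)
        out <- rep(NA_real_, nrow(fst))
        out[as.integer(rownames(s))] <- s[, 1] / l[, 1]
        out
    }
    out <- fst
    out$dxy <- dxy$dxy
    cA <- paste0("pi_", popA)
    cB <- paste0("pi_", popB)
    out[[cA]] <- agg(pis[[cA]])
    out[[cB]] <- agg(pis[[cB]])
    out$pi_mean <- (out[[cA]] + out[[cB]]) / 2
    attr(out, "genome_fst") <- attr(fst, "genome")
    attr(out, "pi_table") <- pis
    out
}
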