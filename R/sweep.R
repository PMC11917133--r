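# Composite-likelihood selective sweep scan (SweepFinder/SweeD family),
# on the folded site frequency spectrum, conditioned on polymorphism.

#' Empirical background folded SFS of a population
#'
#' The folded site frequency spectrum over all of the population's
#' polymorphic sites genome-wide.  Sites with missing calls are
#' down-projected to the smallest common chromosome count by hypergeometric
#' projection (the expected spectrum over all subsamples of that size);
#' projected mass landing on the monomorphic classes is discarded and the
#' spectrum renormalized, so it is conditioned on polymorphism at the
#' projected size.
#'
#' @param vt a [VariantTable-class].
#' @param pm population map; defaults to `colData(vt)$population`.
#' @param pop population label.
#' @param nProject optional even chromosome count to project to; default is
#'   the smallest called count among the population's polymorphic sites.
#' @return a [FoldedSFS-class].
#' @export
backgroundSFS <- function(vt, pm = NULL, pop, nProject = NULL) {
    idx <- .popIndex(vt, pm, pop)
    sc <- .siteCounts(genotypes(vt), idx)
    poly <- sc$nChr >= 2 & sc$alt > 0 & sc$alt < sc$nChr
    if (sum(poly) < 2)
        stop("population ", pop, " has fewer than 2 polymorphic sites")
    nChr <- sc$nChr[poly]
    k <- sc$alt[poly]
    n <- if (is.null(nProject)) min(nChr) else as.integer(nProject)
    if (n < 2 || n > min(nChr))
        stop("nProject must be in [2, smallest called count]")
    counts <- rep(0, n + 1)          # expected counts of derived j = 0..n
    cfg <- unique(cbind(nChr, k))
    for (i in seq_len(nrow(cfg))) {
        m <- cfg[i, 1]
        kk <- cfg[i, 2]
        w <- sum(nChr == m & k == kk)
        j <- 0:n
        counts <- counts + w * stats::dhyper(j, kk, m - kk, n)
    }
    counts[c(1, n + 1)] <- 0          # condition on polymorphism
    half <- n %/% 2
    folded <- vapply(seq_len(half), function(m) {
        if (m == n - m) counts[m + 1] else counts[m + 1] + counts[n - m + 1]
    }, numeric(1))
    FoldedSFS(n, folded / sum(folded))
}

#' Lineage escape probability of the sweep model
#'
#' Probability that a lineage sampled at distance `d` bp from a sweep of
#' per-bp intensity `alpha` recombined off the sweeping haplotype:
#' \eqn{p_e = 1 - e^{-\alpha d}}.
#'
#' @param alpha sweep intensity per bp (>= 0); larger means a harder, more
#'   localized sweep.
#' @param d distance in bp (>= 0).
#' @return escape probability in \[0, 1\]; vectorized.
#' @export
escapeProb <- function(alpha, d) {
    stopifnot(all(alpha >= 0), all(d >= 0))
    1 - exp(-alpha * d)
}

# Exact folded site distribution under the star-genealogy sweep model, as a
# function of the escape probability pe.  probs: background folded SFS for n
# chromosomes.  Each derived class j (unfolded symmetrically) has frequency
# p = j/n; E ~ Binomial(n, pe) lineages escape and are derived
# independently with probability p; the n-E swept lineages form one block,
# derived all-or-none with probability p.  Monomorphic outcomes are dropped
# and the rest renormalized.
.siteProbsPe <- function(probs, n, pe) {
    half <- n %/% 2
    j <- seq_len(n - 1)
    w <- probs[pmin(j, n - j)] / (1 + (j != n - j))
    pE <- stats::dbinom(0:n, n, pe)
    P <- numeric(n + 1)
    for (jj in j) {
        p <- jj / n
        Pj <- numeric(n + 1)
        for (e in 0:n) {
            esc <- stats::dbinom(0:e, e, p)
            kb <- (n - e) + (0:e)             # block derived
            Pj[kb + 1] <- Pj[kb + 1] + pE[e + 1] * p * esc
            Pj[(0:e) + 1] <- Pj[(0:e) + 1] + pE[e + 1] * (1 - p) * esc
        }
        P <- P + w[jj] * Pj
    }
    P[c(1, n + 1)] <- 0
    folded <- vapply(seq_len(half), function(m) {
        if (m == n - m) P[m + 1] else P[m + 1] + P[n - m + 1]
    }, numeric(1))
    Z <- sum(folded)
    if (!is.finite(Z) || Z < 1e-300)
        stop("sweep site distribution underflow (escape probability ~ 0)")
    folded / Z
}

#' Folded site distribution under the sweep model
#'
#' Distribution over folded minor-allele count classes at a polymorphic site
#' a distance `d` from a sweep of intensity `alpha`, given the background
#' spectrum: the star-genealogy transformation with escape probability
#' [escapeProb()].  At `alpha * d = 0` no lineage escapes, every outcome is
#' monomorphic and the polymorphism-conditioned distribution is undefined
#' (an error); as `alpha * d` grows the distribution approaches binomial
#' resampling of the background spectrum.
#'
#' @param sfs a [FoldedSFS-class] background spectrum.
#' @param alpha sweep intensity per bp.
#' @param d distance from the sweep center in bp.
#' @return numeric vector of probabilities over classes
#'   `1..floor(n/2)`, summing to 1.
#' @export
sweepSiteProbs <- function(sfs, alpha, d) {
    .siteProbsPe(sfs@probs, sfs@n, escapeProb(alpha, d))
}

#' Default sweep-intensity grid
#'
#' 24 log-spaced values spanning `1e-8` to `1e-1` per bp, bracketing escape
#' probabilities from ~0 to ~1 over 1 bp to 10 Mb distances.  The neutral
#' model is always scored alongside this grid.
#'
#' @return numeric vector of alpha values.
#' @export
defaultAlphaGrid <- function() 10^seq(-8, -1, length.out = 24)

# Log-probability lookup table over a log-spaced grid of x = alpha * d.
# Rows: x grid; columns: folded classes.
.sweepLogTable <- function(sfs, nX = 160, xMin = 1e-6, xMax = 50) {
    lx <- seq(log(xMin), log(xMax), length.out = nX)
    tab <- t(vapply(lx, function(v)
        log(.siteProbsPe(sfs@probs, sfs@n, 1 - exp(-exp(v)))),
        numeric(sfs@n %/% 2)))
    list(logx = lx, tab = tab)
}

#' Composite-likelihood-ratio sweep scan
#'
#' Scans each chromosome on a grid of equally spaced positions.  At grid
#' position `x`, for each candidate intensity `alpha`, the sweep
#' log-likelihood sums `log P(k_i | alpha, d_i)` (see [sweepSiteProbs()])
#' over the population's polymorphic sites within `maxWindow` of `x`; the
#' null log-likelihood sums the background spectrum probabilities of the
#' same sites.  `CLR(x) = 2 (max_alpha logL_sweep - logL_0)`, with the
#' neutral model included in the maximization so CLR is never negative.
#'
#' Only sites whose called chromosome count equals the spectrum's sample
#' size enter the scan (the background spectrum handles missing data by
#' projection; the per-site likelihood does not).  Site distances are
#' floored at 1 bp.  For speed the per-site distribution is looked up in a
#' precomputed table over `alpha * d`; [sweepSiteProbs()] itself is exact.
#'
#' @param vt a [VariantTable-class].
#' @param pm population map; defaults to `colData(vt)$population`.
#' @param pop population to scan.
#' @param gridCount grid positions per chromosome (default 1000).
#' @param alphaGrid candidate intensities (default [defaultAlphaGrid()]).
#' @param maxWindow maximum site-to-grid-point distance in bp (default 1 Mb).
#' @param sfs optional [FoldedSFS-class] background; computed genome-wide
#'   from `vt` when `NULL`.
#' @param gridPositions optional list (named by chromosome) of explicit grid
#'   positions, overriding `gridCount`.
#' @return a [SweepScan-class].
#' @export
clrScan <- function(vt, pm = NULL, pop, gridCount = 1000,
                    alphaGrid = defaultAlphaGrid(), maxWindow = 1e6,
                    sfs = NULL, gridPositions = NULL) {
    pm <- .resolvePopMap(vt, pm)
    idx <- which(pm == pop)
    if (!length(idx)) stop("population not found in map: ", pop)
    if (is.null(sfs)) sfs <- backgroundSFS(vt, pm, pop)
    n <- sfs@n
    lookup <- .sweepLogTable(sfs)
    nX <- length(lookup$logx)
    sc <- .siteCounts(genotypes(vt), idx)
    usable <- sc$nChr == n & sc$alt > 0 & sc$alt < sc$nChr
    cls <- pmin(sc$alt, sc$nChr - sc$alt)
    logNull <- rep(NA_real_, length(cls))
    logNull[usable] <- log(sfs@probs)[cls[usable]]
    rr <- SummarizedExperiment::rowRanges(vt)
    chromAll <- as.character(GenomicRanges::seqnames(rr))
    posAll <- GenomicRanges::start(rr)
    ci <- contigIndex(vt)
    res <- lapply(names(ci), function(ch) {
        on <- usable & chromAll == ch
        if (is.null(gridPositions)) {
            gp <- round(seq(1, ci[[ch]], length.out = gridCount))
        } else {
            gp <- gridPositions[[ch]]
            if (is.null(gp)) return(NULL)
        }
        if (!any(on)) {
            warning("chromosome ", ch, " has no usable polymorphic sites for ",
                    pop)
            return(data.frame(chrom = ch, pos = gp, clr = 0,
                              alphaHat = NA_real_))
        }
        res <- .clrScanChromCpp(as.numeric(posAll[on]),
                                as.integer(cls[on]), logNull[on],
                                lookup$tab, lookup$logx[1],
                                lookup$logx[2] - lookup$logx[1],
                                as.numeric(gp), alphaGrid, maxWindow)
        data.frame(chrom = ch, pos = gp, clr = res$clr,
                   alphaHat = res$alphaHat, stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, res)
    rownames(tb) <- NULL
    new("SweepScan", population = pop, table = tb,
        params = list(alphaGrid = alphaGrid, maxWindow = maxWindow,
                      n = n, gridCount = gridCount))
}
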