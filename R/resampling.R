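# Permutation tests: genome-wide F_ST significance and the OGD x sweep
# association.

.permResult <- function(observed, nullDraws, seed, statistic) {
    p <- (1 + sum(nullDraws >= observed)) / (length(nullDraws) + 1)
    new("PermutationResult", observed = observed,
        nullDraws = as.numeric(nullDraws), p = p,
        seed = as.integer(seed), statistic = statistic)
}

# Genome-wide theta from a genotype matrix and two column index sets.
.genomeTheta <- function(g, idxA, idxB) {
    a <- .siteCounts(g, idxA)
    b <- .siteCounts(g, idxB)
    comp <- .wcComponents(a$nDip, a$alt, a$het, b$nDip, b$alt, b$het)
    tot <- comp$a + comp$b + comp$c
    use <- !is.na(tot) & tot > 0
    if (!any(use)) return(NA_real_)
    sum(comp$a[use]) / sum(tot[use])
}

#' Label-permutation test for genome-wide F_ST
#'
#' Tests whether the observed genome-wide Weir-Cockerham \eqn{\hat\theta}
#' between two populations exceeds what random sample labelling produces:
#' each replicate shuffles population labels over the pooled samples
#' (preserving group sizes, keeping each sample's genotypes intact) and
#' recomputes \eqn{\hat\theta}.  One-sided, +1-corrected:
#' \eqn{p = (1 + \#\{\theta_{null} \ge \theta_{obs}\}) / (reps + 1)},
#' so p can never be exactly zero and `p = 1/(reps+1)` means the observed
#' value beat every replicate.
#'
#' @param vt a [VariantTable-class].
#' @param pm population map; defaults to `colData(vt)$population`.
#' @param popA,popB population labels.
#' @param reps number of permutation replicates (default 100).
#' @param seed RNG seed.
#' @return a [PermutationResult-class].
#' @export
fstLabelPermutation <- function(vt, pm = NULL, popA, popB, reps = 100,
                                seed = 1) {
    stopifnot(reps >= 1)
    pm <- .resolvePopMap(vt, pm)
    idxA <- which(pm == popA)
    idxB <- which(pm == popB)
    if (length(idxA) < 2 || length(idxB) < 2)
        stop("need at least 2 samples per population")
    g <- genotypes(vt)
    obs <- .genomeTheta(g, idxA, idxB)
    pool <- c(idxA, idxB)
    nA <- length(idxA)
    set.seed(seed)
    nullDraws <- vapply(seq_len(reps), function(i) {
        sh <- sample(pool)
        .genomeTheta(g, sh[seq_len(nA)], sh[-seq_len(nA)])
    }, numeric(1))
    .permResult(obs, nullDraws, seed, sprintf("WC theta %s vs %s", popA, popB))
}

#' Permutation test for OGD x sweep-target association
#'
#' Observed statistic: the number of windows that are both OGDs and sweep
#' targets.  Each replicate redraws `length(sweepWindows)` windows uniformly
#' without replacement from the universe and counts the intersection with
#' the OGD set; one-sided, +1-corrected p.  Under this exchangeable null the
#' p value converges to the hypergeometric upper tail as `reps` grows.
#'
#' @param universe window id universe (typically windows with defined
#'   \eqn{F_{ST}}).
#' @param ogd OGD window ids (subset of `universe`).
#' @param sweepWindows sweep-target window ids (subset of `universe`).
#' @param reps permutation replicates (default 1000).
#' @param seed RNG seed.
#' @param method `"uniform"` (default) resamples window sets uniformly;
#'   `"rotation"` rotates the sweep set circularly along the ordered
#'   universe, preserving its adjacency structure.
#' @return a [PermutationResult-class].
#' @export
ogdSweepAssociation <- function(universe, ogd, sweepWindows, reps = 1000,
                                seed = 1, method = c("uniform", "rotation")) {
    method <- match.arg(method)
    stopifnot(reps >= 1)
    universe <- unique(universe)
    if (length(setdiff(ogd, universe)) || length(setdiff(sweepWindows, universe)))
        stop("ogd and sweepWindows must be subsets of the universe")
    N <- length(universe)
    m <- length(sweepWindows)
    if (m > N) stop("more sweep windows than universe windows")
    inOgd <- universe %in% ogd
    obs <- length(intersect(ogd, sweepWindows))
    set.seed(seed)
    nullDraws <- if (method == "uniform") {
        vapply(seq_len(reps), function(i)
            sum(inOgd[sample.int(N, m)]), numeric(1))
    } else {
        swPos <- which(universe %in% sweepWindows)
        vapply(seq_len(reps), function(i) {
            off <- sample.int(N, 1)
            sum(inOgd[((swPos + off - 1) %% N) + 1])
        }, numeric(1))
    }
    .permResult(obs, nullDraws, seed, "OGD x sweep window overlap")
}
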