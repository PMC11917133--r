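# Independent brute-force oracles.  These re-derive each statistic from
# first principles (explicit loops over haplotype pairs, exhaustive
# enumeration, direct formula transcription) and must stay independent of
# the package's implementation paths.

# Haplotype alleles of one population at one site: j alternate alleles
# among n called chromosomes (order irrelevant for unphased pairwise sums).
.hapAlleles <- function(genoRow) {
    g <- genoRow[!is.na(genoRow)]
    unlist(lapply(g, function(x) c(as.integer(x >= 1), as.integer(x == 2))))
}

# Within-population pi for a window: average pairwise haplotype difference
# per site, summed and divided by the window length.
oracleWindowPi <- function(geno, L) {
    tot <- 0
    for (i in seq_len(nrow(geno))) {
        h <- .hapAlleles(geno[i, ])
        n <- length(h)
        if (n < 2) next
        s <- 0
        for (a in seq_len(n - 1))
            for (b in (a + 1):n)
                s <- s + as.integer(h[a] != h[b])
        tot <- tot + s / choose(n, 2)
    }
    tot / L
}

# Between-population dxy: average difference over all between-population
# haplotype pairs per site, summed, divided by window length.
oracleWindowDxy <- function(genoA, genoB, L) {
    tot <- 0
    for (i in seq_len(nrow(genoA))) {
        hA <- .hapAlleles(genoA[i, ])
        hB <- .hapAlleles(genoB[i, ])
        if (!length(hA) || !length(hB)) next
        s <- 0
        for (a in seq_along(hA))
            for (b in seq_along(hB))
                s <- s + as.integer(hA[a] != hB[b])
        tot <- tot + s / (length(hA) * length(hB))
    }
    tot / L
}

# Weir & Cockerham (1984) theta for two populations: direct symbol-by-symbol
# transcription of the per-site a, b, c components (r = 2), combined as
# ratio of sums.
oracleWCTheta <- function(genoA, genoB) {
    r <- 2
    aSum <- dSum <- 0
    for (i in seq_len(nrow(genoA))) {
        gA <- genoA[i, !is.na(genoA[i, ])]
        gB <- genoB[i, !is.na(genoB[i, ])]
        n1 <- length(gA); n2 <- length(gB)
        if (n1 < 2 || n2 < 2) next
        p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
        h1 <- mean(gA == 1); h2 <- mean(gB == 1)
        nbar <- (n1 + n2) / r
        nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
        pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
        ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
        hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
        a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
             (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             ((r - 1) / r) * ssq - ((2 * nbar - 1) / (4 * nbar)) * hbar)
        cc <- hbar / 2
        if (a + b + cc == 0) next
        aSum <- aSum + a
        dSum <- dSum + a + b + cc
    }
    aSum / dSum
}

# Kendall tau-b by O(n^2) pair counting with tie correction.
oracleKendallTau <- function(x, y) {
    n <- length(x)
    C <- D <- tx <- ty <- 0
    for (i in seq_len(n - 1))
        for (j in (i + 1):n) {
            dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
            if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
            else if (dx == 0) tx <- tx + 1
            else if (dy == 0) ty <- ty + 1
            else if (dx == dy) C <- C + 1
            else D <- D + 1
        }
    n0 <- choose(n, 2)
    (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Upper-tail hypergeometric probability by explicit summation of the pmf,
# written from binomial coefficients.
oracleHyperTail <- function(a, b, cc, d) {
    N <- a + b + cc + d
    K <- a + cc          # family genes
    n <- a + b           # target genes
    ks <- a:min(K, n)
    sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Benjamini-Hochberg step-up by the textbook formula.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    qSorted <- pmin(1, m * p[o] / seq_len(m))
    for (i in seq_len(m)) qSorted[i] <- min(qSorted[i:m])
    q[o] <- qSorted
    q
}

# Exhaustive enumeration of the star-genealogy sweep site distribution for
# small n: every escape indicator vector, escapee allele vector and block
# outcome is enumerated with its probability.
oracleSweepSiteProbs <- function(probs, n, pe) {
    half <- n %/% 2
    j <- seq_len(n - 1)
    w <- probs[pmin(j, n - j)] / (1 + (j != n - j))
    P <- numeric(n + 1)
    for (jj in j) {
        p <- jj / n
        for (escMask in 0:(2^n - 1)) {
            esc <- as.integer(intToBits(escMask))[1:n]
            pEsc <- prod(ifelse(esc == 1, pe, 1 - pe))
            E <- sum(esc)
            for (alleleMask in 0:(2^E - 1)) {
                al <- if (E > 0) as.integer(intToBits(alleleMask))[1:E]
                      else integer(0)
                pAl <- if (E > 0) prod(ifelse(al == 1, p, 1 - p)) else 1
                for (block in 0:1) {
                    pBlock <- if (block == 1) p else 1 - p
                    k <- sum(al) + block * (n - E)
                    P[k + 1] <- P[k + 1] + w[jj] * pEsc * pAl * pBlock
                }
            }
        }
    }
    P[c(1, n + 1)] <- 0
    folded <- vapply(seq_len(half), function(m)
        if (m == n - m) P[m + 1] else P[m + 1] + P[n - m + 1], numeric(1))
    folded / sum(folded)
}

# Small deterministic VariantTable built from an explicit genotype matrix.
makeToyVT <- function(geno, chrom = NULL, pos = NULL, seqlengths = NULL,
                      population = NULL) {
    ns <- nrow(geno)
    if (is.null(chrom)) chrom <- rep("chr1", ns)
    if (is.null(pos)) pos <- seq_len(ns) * 10L
    if (is.null(colnames(geno)))
        colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
    VariantTable(chrom = chrom, pos = pos, ref = rep("A", ns),
                 alt = rep("T", ns), geno = geno, seqlengths = seqlengths,
                 population = population)
}

# Two-population Balding-Nichols matrix generator used by recovery tests
# (independent of the package's scenario machinery).
simTwoPopGeno <- function(nSites, nDip, F, seed) {
    set.seed(seed)
    p <- runif(nSites, 0.05, 0.95)
    g <- matrix(0L, nSites, 2 * nDip)
    for (k in 1:2) {
        pk <- rbeta(nSites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
        for (d in seq_len(nDip))
            g[, (k - 1) * nDip + d] <- rbinom(nSites, 2, pk)
    }
    colnames(g) <- c(sprintf("A%02d", seq_len(nDip)),
                     sprintf("B%02d", seq_len(nDip)))
    g
}
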