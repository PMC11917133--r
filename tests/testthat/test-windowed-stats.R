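test_that("makeWindows tiles contigs, keeping a flagged partial tail", {
    w <- makeWindows(c(chr1 = 1200000), 500000)
    expect_equal(length(w), 3L)
    expect_equal(GenomicRanges::start(w) - 1, c(0, 500000, 1000000))
    expect_equal(GenomicRanges::end(w), c(500000, 1000000, 1200000))
    expect_equal(GenomicRanges::mcols(w)$partial, c(FALSE, FALSE, TRUE))
    # window larger than the contig: one partial window
    w1 <- makeWindows(c(tiny = 1000), 500000)
    expect_equal(length(w1), 1L)
    expect_true(GenomicRanges::mcols(w1)$partial)
    # a 31-chromosome 435.6-Mb genome at 500 kb: each window ~0.125% of
    # the genome, ~880 windows up to per-contig rounding
    ci <- setNames(rep(435.6e6 / 31, 31), paste0("c", 1:31))
    wAll <- makeWindows(ci, 500000)
    expect_true(length(wAll) >= 872 && length(wAll) <= 902)
})

test_that("per-site pi matches its pairwise definition", {
    expect_equal(sitePi(1, 2), 1)            # two chromosomes, one diff
    expect_equal(sitePi(0, 20), 0)           # monomorphic
    expect_equal(sitePi(20, 20), 0)
    expect_equal(sitePi(5, 20), 150 / 380)   # 75 of 190 pairs differ
    expect_true(is.na(sitePi(1, 1)))
})

test_that("window pi equals the brute-force haplotype-pair average", {
    # one het variant in a 1000-bp window -> pi = 1/1000
    g <- matrix(c(1L, 1L), 1, 2)
    vt <- makeToyVT(g, pos = 500L, seqlengths = c(chr1 = 1000),
                    population = c(s01 = "P", s02 = "P"))
    w <- makeWindows(contigIndex(vt), 1000)
    out <- windowPi(vt, windows = w)
    expect_equal(out$pi_P, sitePi(2, 4) / 1000)
    # zero variants -> pi 0
    vt0 <- makeToyVT(matrix(0L, 1, 2), pos = 500L,
                     seqlengths = c(chr1 = 1000),
                     population = c(s01 = "P", s02 = "P"))
    expect_equal(windowPi(vt0, windows = w)$pi_P, 0)
    # 100 random sites (with missingness) vs the haplotype-pair oracle
    set.seed(7)
    geno <- matrix(sample(c(0:2, NA), 100 * 10, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), 100, 10)
    storage.mode(geno) <- "integer"
    vt <- makeToyVT(geno, pos = sort(sample.int(5000, 100)),
                    seqlengths = c(chr1 = 5000),
                    population = setNames(rep("P", 10),
                                          sprintf("s%02d", 1:10)))
    w <- makeWindows(contigIndex(vt), 5000)
    expect_equal(windowPi(vt, windows = w)$pi_P,
                 oracleWindowPi(geno, 5000), tolerance = 1e-12)
})

test_that("window dxy matches the between-population pair oracle and is symmetric", {
    pm <- setNames(rep(c("A", "B"), each = 4), sprintf("s%02d", 1:8))
    # one fixed difference in a 1000-bp window
    g <- matrix(c(rep(0L, 4), rep(2L, 4)), 1, 8)
    vt <- makeToyVT(g, pos = 10L, seqlengths = c(chr1 = 1000),
                    population = pm)
    w <- makeWindows(contigIndex(vt), 1000)
    expect_equal(windowDxy(vt, popA = "A", popB = "B", windows = w)$dxy,
                 1 / 1000)
    # both populations fixed for the same allele -> 0
    g2 <- matrix(2L, 3, 8)
    vt2 <- makeToyVT(g2, seqlengths = c(chr1 = 1000), population = pm)
    expect_equal(windowDxy(vt2, popA = "A", popB = "B", windows = w)$dxy, 0)
    # 50 random sites vs oracle; exact symmetry
    set.seed(11)
    geno <- matrix(sample(c(0:2, NA), 50 * 8, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), 50, 8)
    storage.mode(geno) <- "integer"
    vt3 <- makeToyVT(geno, pos = sort(sample.int(2000, 50)),
                     seqlengths = c(chr1 = 2000), population = pm)
    w3 <- makeWindows(contigIndex(vt3), 2000)
    ab <- windowDxy(vt3, popA = "A", popB = "B", windows = w3)$dxy
    ba <- windowDxy(vt3, popA = "B", popB = "A", windows = w3)$dxy
    expect_identical(ab, ba)
    expect_equal(ab, oracleWindowDxy(geno[, 1:4], geno[, 5:8], 2000),
                 tolerance = 1e-12)
})

test_that("Weir-Cockerham theta matches an independent transcription", {
    pm <- setNames(rep(c("A", "B"), each = 4), sprintf("s%02d", 1:8))
    # fixed difference -> theta = 1
    g <- matrix(c(rep(0L, 4), rep(2L, 4)), 2, 8, byrow = TRUE)
    vt <- makeToyVT(g, population = pm)
    expect_equal(wcFst(vt, popA = "A", popB = "B"), 1)
    # identical genotype configurations in both populations -> theta <= 0
    half <- matrix(c(0L, 1L, 2L, 1L), 3, 4, byrow = TRUE)
    vt2 <- makeToyVT(cbind(half, half), population = pm)
    expect_lte(wcFst(vt2, popA = "A", popB = "B"), 0)
    # 3-site toy vs the symbol-by-symbol 1984 oracle
    set.seed(5)
    geno <- matrix(sample(0:2, 3 * 8, replace = TRUE), 3, 8)
    storage.mode(geno) <- "integer"
    vt3 <- makeToyVT(geno, population = pm)
    expect_equal(wcFst(vt3, popA = "A", popB = "B"),
                 oracleWCTheta(geno[, 1:4], geno[, 5:8]), tolerance = 1e-10)
    # and on a larger random matrix with missing data
    set.seed(6)
    geno <- matrix(sample(c(0:2, NA), 80 * 12, replace = TRUE), 80, 12)
    storage.mode(geno) <- "integer"
    pm2 <- setNames(rep(c("A", "B"), each = 6), sprintf("s%02d", 1:12))
    vt4 <- makeToyVT(geno, population = pm2)
    expect_equal(wcFst(vt4, popA = "A", popB = "B"),
                 oracleWCTheta(geno[, 1:6], geno[, 7:12]), tolerance = 1e-10)
})

test_that("Kendall tau matches the O(n^2) pair-count oracle", {
    x <- 1:10
    expect_equal(kendallTau(x, x * 2 + 1)$tau, 1)
    expect_equal(kendallTau(x, -x)$tau, -1)
    set.seed(9)
    for (i in 1:5) {
        a <- rnorm(7)
        b <- rnorm(7)
        expect_equal(kendallTau(a, b)$tau, oracleKendallTau(a, b),
                     tolerance = 1e-12)
    }
    # ties handled via tau-b
    a <- c(1, 1, 2, 3, 3, 4)
    b <- c(2, 1, 1, 3, 4, 4)
    expect_equal(kendallTau(a, b)$tau, oracleKendallTau(a, b),
                 tolerance = 1e-12)
    expect_true(is.na(kendallTau(rep(1, 5), 1:5)$tau))
})

test_that("100-kb pi aggregates exactly into 500-kb windows", {
    scn <- simScenario(nChrom = 2L, nSites = 600L, sweeps = list(),
                       seed = 21L)
    d <- simulateGenotypes(scn)
    st <- windowStats(d$vt, d$pm, "SA", "ML")
    native <- windowPi(d$vt, d$pm,
                       windows = makeWindows(d$ci, 500000))
    expect_equal(st$pi_SA, native$pi_SA, tolerance = 1e-12)
    expect_equal(st$pi_ML, native$pi_ML, tolerance = 1e-12)
})

test_that("under panmixia mean dxy matches mean cross-population pi", {
    scn <- simScenario(popNames = c("A", "B"), diploids = c(12L, 12L),
                       nChrom = 2L, nSites = 3000L,
                       F = c(1e-4, 1e-4), sweeps = list(), seed = 31L)
    d <- simulateGenotypes(scn)
    st <- windowStats(d$vt, d$pm, "A", "B")
    ok <- !is.na(st$dxy)
    expect_equal(mean(st$dxy[ok]), mean(st$pi_mean[ok]), tolerance = 0.05)
})
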