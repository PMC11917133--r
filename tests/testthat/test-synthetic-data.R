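test_that("simulation is bit-reproducible under a fixed seed", {
    scn <- simScenario(nChrom = 4L, nSites = 400L, seed = 99L)
    a <- simulateDataset(scn)
    b <- simulateDataset(scn)
    expect_identical(genotypes(a$vt), genotypes(b$vt))
    expect_identical(a$genes, b$genes)
})

test_that("scenario validation rejects bad parameters", {
    expect_error(simScenario(F = c(0, 0.05, 0.05)), "F must lie")
    expect_error(simScenario(F = c(0.5, 0.5, 1)), "F must lie")
    expect_error(simScenario(sweeps = list(list(pop = "XX", chrom = "chr1",
                                                center = 1, alpha = 1e-5))),
                 "unknown")
    expect_error(simScenario(enrichFactor = 0.5), "enrichFactor")
})

test_that("Balding-Nichols differentiation is recovered by WC theta", {
    # F -> 0 limit: theta within 0.01 of zero
    g0 <- simTwoPopGeno(20000, 20, 1e-4, seed = 201)
    pm <- setNames(rep(c("A", "B"), each = 20), colnames(g0))
    vt0 <- makeToyVT(g0, pos = seq_len(nrow(g0)), population = pm)
    expect_lt(abs(wcFst(vt0, popA = "A", popB = "B")), 0.01)
    # F = 0.05: estimate lands in [0.04, 0.06]
    g5 <- simTwoPopGeno(20000, 20, 0.05, seed = 202)
    vt5 <- makeToyVT(g5, pos = seq_len(nrow(g5)), population = pm)
    th <- wcFst(vt5, popA = "A", popB = "B")
    expect_gt(th, 0.04)
    expect_lt(th, 0.06)
    # monotonicity in F with paired seeds
    ths <- vapply(c(0.01, 0.05, 0.10), function(F) {
        g <- simTwoPopGeno(8000, 15, F, seed = 300)
        p <- setNames(rep(c("A", "B"), c(15, 15)), colnames(g))
        wcFst(makeToyVT(g, pos = seq_len(nrow(g)), population = p),
              popA = "A", popB = "B")
    }, numeric(1))
    expect_true(all(diff(ths) > 0))
})

test_that("sweep injection fixes the target population at the center", {
    # a site exactly at the center has escape probability 0: monomorphic
    pm <- setNames(rep(c("A", "B"), each = 5), sprintf("s%02d", 1:10))
    geno <- matrix(1L, 20, 10)
    vt <- makeToyVT(geno, pos = c(1000L, sort(sample.int(9e5, 19) + 1e5)),
                    seqlengths = c(chr1 = 1e6), population = pm)
    out <- injectSweep(vt, pop = "A", chrom = "chr1", center = 1000,
                       alpha = 1e-6, seed = 1)
    gA <- genotypes(out)[1, 1:5]
    expect_true(sum(gA) %in% c(0L, 10L))
    gB <- genotypes(out)[, 6:10]
    expect_identical(gB, genotypes(vt)[, 6:10])  # other population untouched
})

test_that("far from the sweep the injection is binomial resampling of the SFS", {
    # alpha*d -> infinity: new counts ~ Binomial(n, k0/n); chi-square GOF
    set.seed(77)
    nDip <- 10L
    geno <- matrix(rbinom(10000 * nDip, 2, 0.3), 10000, nDip)
    storage.mode(geno) <- "integer"
    pm <- setNames(rep("A", nDip), sprintf("s%02d", 1:nDip))
    vt <- makeToyVT(geno, pos = sort(sample.int(2e6, 10000)),
                    seqlengths = c(chr1 = 2e6), population = pm)
    out <- injectSweep(vt, pop = "A", chrom = "chr1", center = 0,
                       alpha = 10, seed = 2)   # pe = 1 at every site
    k0 <- rowSums(geno)
    k1 <- rowSums(genotypes(out))
    n <- 2 * nDip
    # expected counts per outcome class, summed over sites
    expected <- rowSums(vapply(seq_along(k0), function(i)
        dbinom(0:n, n, k0[i] / n), numeric(n + 1)))
    observed <- tabulate(k1 + 1L, nbins = n + 1)
    keep <- expected >= 5
    chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep]) +
        (sum(observed[!keep]) - sum(expected[!keep]))^2 /
            max(sum(expected[!keep]), 1)
    p <- pchisq(chi2, df = sum(keep), lower.tail = FALSE)
    expect_gt(p, 0.01)
})

test_that("the sweep depresses diversity at its center", {
    hits <- 0L
    for (s in 1:20) {
        scn <- simScenario(popNames = "A", diploids = 10L, nChrom = 1L,
                           nSites = 2000L, F = 0.05,
                           sweeps = list(list(pop = "A", chrom = "chr1",
                                              center = 1e6, alpha = 1e-5)),
                           seed = as.integer(400 + s))
        d <- simulateDataset(scn)
        pi100 <- windowPi(d$vt, d$pm, size = 100000)
        center <- which(pi100$start <= 1e6 & pi100$end > 1e6)
        if (pi100$pi_A[center] < median(pi100$pi_A)) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("gene annotations are family-enriched only inside sweep regions", {
    ci <- c(chr1 = 5e6, chr2 = 5e6)
    regions <- data.frame(chrom = "chr1", start = 1e6, end = 1.5e6)
    # null case: enrichFactor 1 leaves the family fraction flat
    g1 <- simulateAnnotations(ci, regions, nGenes = 50000, enrichFactor = 1,
                              seed = 501)
    inR <- g1$chrom == "chr1" & g1$start < 1.5e6 & g1$end > 1e6
    tt <- prop.test(c(sum(g1$family[inR] == "CYP"),
                      sum(g1$family[!inR] == "CYP")),
                    c(sum(inR), sum(!inR)))
    expect_gt(tt$p.value, 0.01)
    # enriched case feeds through to a significant Fisher test
    g20 <- simulateAnnotations(ci, regions, nGenes = 4000, enrichFactor = 20,
                               seed = 502)
    target <- genesInRegions(g20, regions)
    fe <- familyEnrichment(g20, target, "CYP")
    expect_gte(fe$a, 8)
    expect_lt(fe$p, 0.05)
    # zero sweep regions: a valid table, no enrichment signal
    g0 <- simulateAnnotations(ci, regions[0, ], nGenes = 2000,
                              enrichFactor = 20, seed = 503)
    expect_equal(nrow(g0), 2000L)
    expect_false(anyDuplicated(g0$gene_id) > 0)
})
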