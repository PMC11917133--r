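# Internal helpers shared across modules.

# Deterministic stage-seed splitter: one user seed fans out to per-stage
# seeds so stages stay reproducible independently of execution order.
.splitSeed <- function(seed, stage) {
    s <- (as.numeric(seed) %% 2147483647) + 1
    for (ch in utf8ToInt(as.character(stage)))
        s <- (s * 48271 + ch) %% 2147483647
    as.integer(s)
}

# Resolve a population map against a VariantTable: returns a named character
# vector aligned to colnames(vt).  pm = NULL falls back to colData$population.
.resolvePopMap <- function(vt, pm = NULL) {
    if (is.null(pm)) pm <- populations(vt)
    if (is.null(pm))
        stop("no population map: pass `pm` or set colData$population")
    pm <- stats::setNames(as.character(pm), names(pm))
    miss <- setdiff(colnames(vt), names(pm))
    if (length(miss))
        stop("samples without population label: ", paste(miss, collapse = ", "))
    pm[colnames(vt)]
}

.popIndex <- function(vt, pm, pop) {
    pm <- .resolvePopMap(vt, pm)
    idx <- which(pm == pop)
    if (!length(idx)) stop("population not found in map: ", pop)
    idx
}

# Per-site summaries for a set of sample columns: called chromosomes,
# alternate-allele count, heterozygote count, called diploids.
.siteCounts <- function(geno, idx) {
    g <- geno[, idx, drop = FALSE]
    called <- !is.na(g)
    nDip <- rowSums(called)
    list(nDip = nDip,
         nChr = 2 * nDip,
         alt = rowSums(g, na.rm = TRUE),
         het = rowSums(g == 1L, na.rm = TRUE))
}

# Overlap of half-open [start, end) intervals on shared contigs.  Integer
# coordinates let half-open [a, b) map exactly to closed [a+1, b].
.halfOpenOverlaps <- function(qChrom, qStart, qEnd, sChrom, sStart, sEnd) {
    stopifnot(all(qEnd > qStart), all(sEnd > sStart))
    q <- GenomicRanges::GRanges(qChrom, IRanges::IRanges(qStart + 1, qEnd))
    s <- GenomicRanges::GRanges(sChrom, IRanges::IRanges(sStart + 1, sEnd))
    GenomeInfoDb::seqlevels(s) <- union(GenomeInfoDb::seqlevels(s),
                                        GenomeInfoDb::seqlevels(q))
    GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(s)
    IRanges::findOverlaps(q, s)
}

# Window id strings in BED convention, "chrom:start0-end0".
.windowIds <- function(windows) {
    paste0(as.character(GenomicRanges::seqnames(windows)), ":",
           GenomicRanges::start(windows) - 1L, "-",
           GenomicRanges::end(windows))
}
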