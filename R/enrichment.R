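# Gene-family and GO-term overrepresentation inside sweep-targeted OGDs.

#' Genes overlapping a set of regions
#'
#' A gene is in-target when its half-open interval intersects any region;
#' a gene abutting a region boundary (touching without overlap) is not.
#' Genes overlapping several regions are counted once (set semantics).
#'
#' @param genes gene table (`gene_id`, `chrom`, `start`, `end`, 0-based
#'   half-open; see [readGeneTable()]).
#' @param regions regions as a `GRanges` (e.g. windows from
#'   [makeWindows()]) or a data.frame with `chrom`, `start`, `end` in the
#'   half-open convention.
#' @return character vector of in-target `gene_id`s.
#' @export
genesInRegions <- function(genes, regions) {
    if (is(regions, "GRanges")) {
        regions <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(regions)),
            start = GenomicRanges::start(regions) - 1,
            end = GenomicRanges::end(regions))
    }
    if (!nrow(regions) || !nrow(genes)) return(character())
    hits <- .halfOpenOverlaps(genes$chrom, genes$start, genes$end,
                              regions$chrom, regions$start, regions$end)
    unique(genes$gene_id[S4Vectors::queryHits(hits)])
}

.fisher2x2 <- function(a, b, cc, d) {
    # one-tailed (greater) Fisher = hypergeometric upper tail
    p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    list(p = p, or = or)
}

#' Gene-family overrepresentation in a target gene set
#'
#' One-tailed (greater) Fisher's exact test on the 2x2 table of family
#' membership against target membership, over the universe of all genes in
#' the table.
#'
#' @param genes gene table (see [readGeneTable()]).
#' @param targetSet character vector of in-target `gene_id`s (subset of the
#'   universe).
#' @param family family label to test (e.g. `"CYP"`).
#' @return one-row data.frame: `label`, the 2x2 counts `a` (target &
#'   family), `b` (target & other), `c` (rest & family), `d` (rest &
#'   other), `odds_ratio`, `p`, `q` (equal to `p` for a single test).
#' @export
familyEnrichment <- function(genes, targetSet, family) {
    if (!nrow(genes)) stop("empty gene universe")
    bad <- setdiff(targetSet, genes$gene_id)
    if (length(bad))
        stop("targetSet contains ids outside the gene universe: ", bad[1])
    inT <- genes$gene_id %in% targetSet
    inF <- genes$family == family
    a <- sum(inT & inF)
    b <- sum(inT & !inF)
    cc <- sum(!inT & inF)
    d <- sum(!inT & !inF)
    ft <- .fisher2x2(a, b, cc, d)
    data.frame(label = family, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$or, p = ft$p, q = ft$p,
               stringsAsFactors = FALSE)
}

#' GO-term overrepresentation with BH FDR control
#'
#' One-tailed Fisher's exact test per GO term carried by at least one
#' target gene, with Benjamini-Hochberg adjustment across all tested terms.
#' Terms are flat labels (no GO-graph propagation).
#'
#' @param genes gene table; the `go` column holds comma-separated term ids
#'   (may be empty).
#' @param targetSet character vector of in-target `gene_id`s.
#' @param fdrThreshold report terms with `q < fdrThreshold` (default 0.1).
#' @param returnAll if `TRUE`, return every tested term (with a
#'   `significant` flag) instead of only those passing the threshold.
#' @return data.frame of [familyEnrichment()]-shaped rows (one per term),
#'   sorted by `q`.
#' @export
goOverrepresentation <- function(genes, targetSet, fdrThreshold = 0.1,
                                 returnAll = FALSE) {
    terms <- strsplit(ifelse(is.na(genes$go), "", genes$go), ",", fixed = TRUE)
    terms <- lapply(terms, function(x) unique(x[nzchar(x)]))
    inT <- genes$gene_id %in% targetSet
    tested <- unique(unlist(terms[inT]))
    empty <- data.frame(label = character(), a = integer(), b = integer(),
                        c = integer(), d = integer(), odds_ratio = numeric(),
                        p = numeric(), q = numeric(),
                        significant = logical())
    if (!length(tested)) return(empty)
    nT <- sum(inT)
    nU <- nrow(genes)
    rows <- lapply(tested, function(tm) {
        has <- vapply(terms, function(x) tm %in% x, logical(1))
        a <- sum(inT & has)
        b <- nT - a
        cc <- sum(has) - a
        d <- nU - nT - cc
        ft <- .fisher2x2(a, b, cc, d)
        data.frame(label = tm, a = a, b = b, c = cc, d = d,
                   odds_ratio = ft$or, p = ft$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$q, out$p), , drop = FALSE]
    out$significant <- out$q < fdrThreshold
    rownames(out) <- NULL
    if (returnAll) out else out[out$significant, , drop = FALSE]
}
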