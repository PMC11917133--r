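# Rank-based outlier calling: F_ST / d_XY outliers, OGDs, sweep loci.

#' Top-fraction outliers of a ranked statistic
#'
#' Returns the ids of the `ceiling(fraction * N)` highest values, after
#' excluding undefined (`NA`) values; ties at the cut are all included, so
#' the returned set may exceed the nominal count.  The call is invariant
#' under any strictly monotone transform of the values.
#'
#' @param values numeric vector of the statistic.
#' @param ids ids parallel to `values`; defaults to `names(values)` or
#'   indices.
#' @param fraction fraction in (0, 1), e.g. 0.02 for the top 2%.
#' @return character (or integer) vector of outlier ids; empty when no
#'   defined values.
#' @export
topFraction <- function(values, ids = NULL, fraction) {
    stopifnot(fraction > 0, fraction < 1)
    if (is.null(ids))
        ids <- if (!is.null(names(values))) names(values)
               else seq_along(values)
    stopifnot(length(ids) == length(values))
    ok <- !is.na(values)
    if (!any(ok)) return(ids[0])
    v <- values[ok]
    k <- ceiling(fraction * length(v))
    thr <- sort(v, decreasing = TRUE)[k]
    ids[ok][v >= thr]
}

#' Call outliers of genetic differentiation (OGDs)
#'
#' A window is an OGD when it is simultaneously an \eqn{F_{ST}} outlier and
#' a \eqn{d_{XY}} outlier: the set intersection.
#'
#' @param fstOut,dxyOut outlier id sets over the same window universe.
#' @return id vector of OGD windows.
#' @export
callOGD <- function(fstOut, dxyOut) intersect(fstOut, dxyOut)

#' Call sweep-targeted loci from a CLR scan
#'
#' Grid points in the genome-wide top `fraction` of CLR values (ties
#' included) are outliers; maximal runs of at least two consecutive
#' above-threshold grid points on a chromosome become sweep loci, and
#' isolated single points are discarded.  Locus bp intervals extend half a
#' grid step beyond the first and last grid point (0-based half-open).
#'
#' @param scan a [SweepScan-class] (all chromosomes of one population).
#' @param fraction outlier fraction of grid points (default 0.0005, the top
#'   0.05%).
#' @param minRun minimum run length of consecutive outlier grid points
#'   (default 2).
#' @return data.frame of loci: `chrom`, `start`, `end` (0-based half-open
#'   bp), `n_grid`, `max_clr`; zero rows when nothing qualifies.
#' @export
callSweepLoci <- function(scan, fraction = 0.0005, minRun = 2L) {
    tb <- scanTable(scan)
    out <- topFraction(tb$clr, seq_len(nrow(tb)), fraction)
    flag <- logical(nrow(tb))
    flag[out] <- TRUE
    loci <- list()
    for (ch in unique(tb$chrom)) {
        ii <- which(tb$chrom == ch)
        pos <- tb$pos[ii]
        step <- if (length(pos) > 1) stats::median(diff(pos)) else 1
        r <- rle(flag[ii])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        keep <- r$values & r$lengths >= minRun
        for (ri in which(keep)) {
            sel <- ii[starts[ri]:ends[ri]]
            loci[[length(loci) + 1]] <- data.frame(
                chrom = ch,
                start = max(0, tb$pos[sel[1]] - floor(step / 2)),
                end = tb$pos[sel[length(sel)]] + ceiling(step / 2),
                n_grid = length(sel),
                max_clr = max(tb$clr[sel]),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(loci))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_grid = integer(),
                          max_clr = numeric()))
    do.call(rbind, loci)
}

#' Project sweep loci onto windows
#'
#' A window overlaps a locus when their half-open bp intervals intersect.
#'
#' @param loci data.frame from [callSweepLoci()] (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param windows `GRanges` from [makeWindows()].
#' @return character vector of overlapped window ids.
#' @export
lociToWindows <- function(loci, windows) {
    if (!nrow(loci)) return(character())
    hits <- .halfOpenOverlaps(loci$chrom, loci$start, loci$end,
                              as.character(GenomicRanges::seqnames(windows)),
                              GenomicRanges::start(windows) - 1,
                              GenomicRanges::end(windows))
    unique(names(windows)[S4Vectors::subjectHits(hits)])
}
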