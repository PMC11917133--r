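# VCF and table input/output, plus the site-level hard filters.

#' Read biallelic SNVs from a VCF file
#'
#' Reads a VCF (v4.x, plain or bgzipped) and returns only biallelic SNV
#' records as a [VariantTable-class].  Genotypes are coded as alternate-allele
#' counts; phased (`0|1`) and unphased (`0/1`) calls are treated identically,
#' and any genotype containing a missing allele (`./.`, `./1`, ...) becomes
#' `NA`.  The numeric hard-filter annotations `QD`, `FS`, `MQ`, `MQRankSum`
#' and `ReadPosRankSum` are carried along when present in the INFO column.
#'
#' @param path path to a VCF file.
#' @param samples optional character vector restricting the sample columns;
#'   a requested sample absent from the file is an error.
#' @return a [VariantTable-class]; multiallelic records and indels are dropped.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "OGDscan")
#' vt <- readVCF(vcf)
#' genotypes(vt)
#' @export
readVCF <- function(path, samples = NULL) {
    vcf <- tryCatch(
        suppressWarnings(VariantAnnotation::readVcf(path)),
        error = function(e)
            stop("malformed VCF '", path, "': ", conditionMessage(e),
                 call. = FALSE))
    if (!is.null(samples)) {
        miss <- setdiff(samples, colnames(vcf))
        if (length(miss))
            stop("sample(s) not present in VCF: ", paste(miss, collapse = ", "))
        vcf <- vcf[, samples]
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    one <- S4Vectors::elementNROWS(altL) == 1L
    alts <- rep(NA_character_, length(refs))
    alts[one] <- as.character(unlist(altL[one]))
    keep <- one & nchar(refs) == 1L & !is.na(alts) & nchar(alts) == 1L &
        refs %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T")
    if (!any(keep))
        return(VariantTable(character(), integer(), character(), character(),
                            matrix(integer(), 0, ncol(vcf),
                                   dimnames = list(NULL, colnames(vcf)))))
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop("malformed VCF '", path, "': no GT field in FORMAT")
    gt <- gt[keep, , drop = FALSE]
    geno <- .decodeGT(gt)
    inf <- VariantAnnotation::info(vcf)
    info <- data.frame(row.names = seq_len(sum(keep)))
    for (k in .INFO_KEYS)
        if (k %in% colnames(inf))
            info[[k]] <- as.numeric(inf[[k]])[keep]
    sl <- GenomeInfoDb::seqlengths(vcf)
    if (all(is.na(sl))) sl <- NULL
    VariantTable(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                 pos = GenomicRanges::start(rr)[keep],
                 ref = refs[keep], alt = alts[keep],
                 geno = geno, info = info, seqlengths = sl)
}

# Map GT strings to {0,1,2,NA}; a "." allele anywhere means missing.
.decodeGT <- function(gt) {
    u <- unique(as.vector(gt))
    code <- vapply(u, function(s) {
        al <- strsplit(gsub("|", "/", s, fixed = TRUE), "/", fixed = TRUE)[[1]]
        if (length(al) != 2L || any(al == "."))
            return(NA_integer_)
        v <- suppressWarnings(as.integer(al))
        if (anyNA(v) || any(v < 0L) || any(v > 1L))
            stop("malformed genotype field: '", s, "'")
        sum(v)
    }, integer(1))
    m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
    m
}

#' Write a VariantTable as VCF
#'
#' Emits a minimal VCF v4.2 with contig lines, the retained INFO annotations
#' and a GT-only FORMAT.  Missing genotypes are written as `./.`.
#'
#' @param vt a [VariantTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(vt, path) {
    sl <- contigIndex(vt)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(sl), as.integer(sl)),
             sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                     .INFO_KEYS, .INFO_KEYS),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(vt)), collapse = "\t"))
    rr <- SummarizedExperiment::rowRanges(vt)
    md <- GenomicRanges::mcols(rr)
    infoStr <- vapply(seq_along(rr), function(i) {
        vals <- vapply(.INFO_KEYS, function(k) md[[k]][i], numeric(1))
        ok <- !is.na(vals)
        if (!any(ok)) return(".")
        paste(paste0(.INFO_KEYS[ok], "=", format(vals[ok], digits = 6,
                                                 trim = TRUE)),
              collapse = ";")
    }, character(1))
    gmap <- c("0/0", "0/1", "1/1")
    g <- genotypes(vt)
    gs <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    gs[ok] <- gmap[g[ok] + 1L]
    body <- paste(as.character(GenomicRanges::seqnames(rr)),
                  GenomicRanges::start(rr), ".", md$ref, md$alt, ".", "PASS",
                  infoStr, "GT",
                  apply(gs, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Hard-filter SNV sites on GATK-style annotations
#'
#' Removes sites failing any of: `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`.  A site missing an
#' annotation passes that criterion (it cannot be evaluated, so it does not
#' exclude).  Site order is preserved and the filter is idempotent.
#'
#' @param vt a [VariantTable-class].
#' @return the filtered [VariantTable-class].
#' @export
hardFilterSites <- function(vt) {
    md <- GenomicRanges::mcols(SummarizedExperiment::rowRanges(vt))
    flag <- function(x, bad) !is.na(x) & bad(x)
    drop <- flag(md$QD, function(x) x < 2.0) |
        flag(md$FS, function(x) x > 60.0) |
        flag(md$MQ, function(x) x < 40.0) |
        flag(md$MQRankSum, function(x) x < -12.5) |
        flag(md$ReadPosRankSum, function(x) x < -8.0)
    vt[!drop, ]
}

#' Drop sites with any missing genotype
#'
#' Retains only sites at which every sample has a called genotype.
#'
#' @param vt a [VariantTable-class].
#' @return the filtered [VariantTable-class].
#' @export
dropMissingSites <- function(vt) {
    keep <- rowSums(is.na(genotypes(vt))) == 0L
    vt[keep, ]
}

#' Read a sample-to-population map
#'
#' Two-column whitespace-separated text (`sample population`); `#` comment
#' lines and blank lines are ignored.
#'
#' @param path path to the map file.
#' @return named character vector, sample -> population label.
#' @export
readPopulationMap <- function(path) {
    ln <- readLines(path)
    ln <- sub("#.*", "", ln)
    ln <- trimws(ln)
    ln <- ln[nzchar(ln)]
    if (!length(ln)) return(stats::setNames(character(), character()))
    parts <- strsplit(ln, "[ \t]+")
    bad <- which(vapply(parts, length, integer(1)) < 2L)
    if (length(bad))
        stop("population map line ", bad[1], " does not have two fields")
    sm <- vapply(parts, `[`, character(1), 1L)
    pp <- vapply(parts, `[`, character(1), 2L)
    if (anyDuplicated(sm))
        stop("duplicate sample in population map: ",
             sm[duplicated(sm)][1])
    stats::setNames(pp, sm)
}

#' @rdname readPopulationMap
#' @param pm named character vector (sample -> population).
#' @export
writePopulationMap <- function(pm, path) {
    writeLines(paste(names(pm), pm, sep = "\t"), path)
    invisible(path)
}

#' Read or write a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `start`, `end`
#' (0-based half-open bp), `family`, `go` (comma-separated GO terms, may be
#' empty).
#'
#' @param path file path.
#' @return `readGeneTable`: a data.frame with those columns.
#' @export
readGeneTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = c(go = "character"))
    need <- c("gene_id", "chrom", "start", "end", "family", "go")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("gene table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene table")
    df
}

#' @rdname readGeneTable
#' @param genes a gene table data.frame.
#' @export
writeGeneTable <- function(genes, path) {
    utils::write.table(genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read or write a tab-separated results table
#'
#' Tables carry a header line; window coordinates are BED-style 0-based
#' half-open.  Numeric values round-trip to at least 12 significant digits.
#'
#' @param df a data.frame.
#' @param path file path.
#' @export
writeStatsTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]]))
            out[[j]] <- sprintf("%.15g", out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeStatsTable
#' @export
readStatsTable <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path file path.
#' @export
writeBED <- function(df, path) {
    cols <- df[, intersect(c("chrom", "start", "end", "name"), colnames(df)),
               drop = FALSE]
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
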