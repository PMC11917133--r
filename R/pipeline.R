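# Pipeline orchestration: simulate/read -> filter -> windowed stats ->
# sweep scan -> outliers -> permutation tests -> enrichment, plus the PCA
# quick-look.

#' Assemble and validate a run configuration
#'
#' Defaults are the scan's canonical thresholds: 500-kb \eqn{F_{ST}}/
#' \eqn{d_{XY}} windows, 100-kb native \eqn{\pi} windows, top 2% outlier
#' fractions, top 0.05% CLR fraction on a grid of 1000 positions per
#' chromosome, 100 label-permutation and 1000 association replicates, and
#' FDR < 0.1 for GO terms.
#'
#' @param scenario a [SimScenario-class] for synthetic input, or `NULL` to
#'   read files.
#' @param vcf,popmap,genes input file paths (used when `scenario` is NULL).
#' @param windowSize,piWindowSize window sizes in bp.
#' @param fstFraction,dxyFraction,clrFraction outlier fractions in (0, 1).
#' @param gridCount CLR grid positions per chromosome.
#' @param maxWindow CLR scan site-distance bound in bp.
#' @param fstPermReps,assocReps permutation replicate counts.
#' @param fdr GO-term FDR threshold.
#' @param hardFilter,dropMissing logical stage switches.
#' @param seed master seed; every random stage derives its own seed from it.
#' @param outDir optional output directory for result tables.
#' @return a validated config (list).
#' @export
runConfig <- function(scenario = simScenario(), vcf = NULL, popmap = NULL,
                      genes = NULL, windowSize = 500000,
                      piWindowSize = 100000, fstFraction = 0.02,
                      dxyFraction = 0.02, clrFraction = 0.0005,
                      gridCount = 1000, maxWindow = 1e6, fstPermReps = 100,
                      assocReps = 1000, fdr = 0.1, hardFilter = TRUE,
                      dropMissing = TRUE, seed = 1, outDir = NULL) {
    cfg <- list(scenario = scenario, vcf = vcf, popmap = popmap,
                genes = genes, windowSize = windowSize,
                piWindowSize = piWindowSize, fstFraction = fstFraction,
                dxyFraction = dxyFraction, clrFraction = clrFraction,
                gridCount = gridCount, maxWindow = maxWindow,
                fstPermReps = fstPermReps, assocReps = assocReps, fdr = fdr,
                hardFilter = hardFilter, dropMissing = dropMissing,
                seed = seed, outDir = outDir)
    for (f in c("fstFraction", "dxyFraction", "clrFraction", "fdr"))
        if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
            stop(f, " must lie in (0, 1)")
    if (cfg$windowSize <= 0 || cfg$piWindowSize <= 0)
        stop("window sizes must be positive")
    if (is.null(cfg$scenario) && (is.null(cfg$vcf) || is.null(cfg$popmap)))
        stop("either a scenario or vcf + popmap paths are required")
    cfg
}

#' Read a YAML run configuration
#'
#' Scalar fields of [runConfig()] plus an optional `scenario:` block whose
#' entries are [simScenario()] arguments (`sweeps:` as a list of maps).
#'
#' @param path YAML file path.
#' @return a validated config (list).
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    scn <- NULL
    if (!is.null(y$scenario)) {
        sa <- y$scenario
        if (!is.null(sa$familyProbs)) sa$familyProbs <- unlist(sa$familyProbs)
        scn <- do.call(simScenario, sa)
    }
    y$scenario <- scn
    do.call(runConfig, y)
}

#' Genotype PCA quick-look
#'
#' Principal components of the centered (optionally frequency-standardized)
#' genotype matrix, for cluster recovery checks.  Missing genotypes are
#' mean-imputed per site; invariant sites are dropped.
#'
#' @param vt a [VariantTable-class].
#' @param k number of components to return (default 2).
#' @param standardize divide each site by \eqn{\sqrt{p(1-p)}}.
#' @return list: `scores` (samples x k), `varianceFraction` (length k),
#'   full `sdev`.
#' @export
pcaQuicklook <- function(vt, k = 2, standardize = TRUE) {
    if (nrow(vt) < 2 || ncol(vt) < 2)
        stop("need at least 2 sites and 2 samples")
    g <- t(genotypes(vt))          # samples x sites
    mu <- colMeans(g, na.rm = TRUE)
    for (j in which(colSums(is.na(g)) > 0))
        g[is.na(g[, j]), j] <- mu[j]
    keep <- apply(g, 2, function(x) stats::var(x) > 0)
    g <- g[, keep, drop = FALSE]
    mu <- mu[keep]
    if (!ncol(g)) stop("all sites invariant")
    gc <- sweep(g, 2, mu)
    if (standardize) {
        p <- mu / 2
        gc <- sweep(gc, 2, sqrt(pmax(p * (1 - p), 1e-12)), "/")
    }
    pc <- stats::prcomp(gc, center = FALSE, scale. = FALSE)
    k <- min(k, ncol(pc$x))
    vf <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         varianceFraction = vf[seq_len(k)], sdev = pc$sdev)
}

#' Run the full genome-scan pipeline
#'
#' simulate/read -> hard filter -> missingness filter -> windowed
#' \eqn{F_{ST}}/\eqn{d_{XY}}/\eqn{\pi} per population pair (with Kendall
#' \eqn{\tau} between \eqn{d_{XY}} and mean \eqn{\pi}) -> genome-wide
#' \eqn{F_{ST}} label-permutation tests -> per-population CLR sweep scans ->
#' rank-based outliers, OGDs and sweep loci -> OGD x sweep association
#' tests -> gene-family and GO enrichment inside sweep-targeted OGDs.
#'
#' The association universe for a population is the set of windows with
#' defined \eqn{F_{ST}} in both of its pairs; its OGD set is the union over
#' those pairs.  Fully deterministic given `cfg$seed`: every random stage
#' derives its own seed from it.
#'
#' @param cfg a config from [runConfig()] / [readRunConfig()].
#' @return a report list: `config`, `counts`, `stats` (per pair), `kendall`,
#'   `fstPermutation`, `scans`, `sweepLoci`, `outliers`, `association`,
#'   `enrichment`, `pca`.  Result tables are written to `cfg$outDir` when
#'   set.
#' @export
runPipeline <- function(cfg) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    # --- data ---------------------------------------------------------
    dat <- stage("data", {
        if (!is.null(cfg$scenario)) {
            scn <- cfg$scenario
            scn@seed <- .splitSeed(cfg$seed, "simulate")
            simulateDataset(scn)
        } else {
            vt <- readVCF(cfg$vcf)
            pm <- readPopulationMap(cfg$popmap)
            cd <- SummarizedExperiment::colData(vt)
            cd$population <- unname(pm[rownames(cd)])
            SummarizedExperiment::colData(vt) <- cd
            genes <- if (!is.null(cfg$genes)) readGeneTable(cfg$genes)
                     else NULL
            list(vt = vt, pm = pm, ci = contigIndex(vt), genes = genes,
                 regions = NULL, scenario = NULL)
        }
    })
    vt <- dat$vt
    pm <- .resolvePopMap(vt, dat$pm)
    nInput <- nrow(vt)
    if (isTRUE(cfg$hardFilter)) vt <- stage("filter", hardFilterSites(vt))
    if (isTRUE(cfg$dropMissing)) vt <- stage("filter", dropMissingSites(vt))
    pops <- sort(unique(pm))
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    pairName <- vapply(pairs, paste, character(1), collapse = "-")
    windows <- makeWindows(contigIndex(vt), cfg$windowSize)
    # --- windowed statistics ------------------------------------------
    stats <- stage("stats", {
        st <- lapply(pairs, function(pr)
            windowStats(vt, pm, pr[1], pr[2], windowSize = cfg$windowSize,
                        piWindowSize = cfg$piWindowSize))
        names(st) <- pairName
        st
    })
    kendall <- lapply(stats, function(tb) {
        ok <- !is.na(tb$dxy) & !is.na(tb$pi_mean)
        if (sum(ok) >= 3) kendallTau(tb$pi_mean[ok], tb$dxy[ok])
        else list(tau = NA_real_, p = NA_real_)
    })
    fstPerm <- stage("fst-permutation", {
        out <- lapply(seq_along(pairs), function(i)
            fstLabelPermutation(vt, pm, pairs[[i]][1], pairs[[i]][2],
                                reps = cfg$fstPermReps,
                                seed = .splitSeed(cfg$seed,
                                                  paste0("fstperm", i))))
        names(out) <- pairName
        out
    })
    # --- sweep scans and outliers -------------------------------------
    scans <- stage("scan", {
        out <- lapply(pops, function(p)
            clrScan(vt, pm, p, gridCount = cfg$gridCount,
                    maxWindow = cfg$maxWindow))
        names(out) <- pops
        out
    })
    sweepLoci <- lapply(scans, callSweepLoci, fraction = cfg$clrFraction)
    sweepWin <- lapply(sweepLoci, lociToWindows, windows = windows)
    outl <- stage("outliers", {
        out <- lapply(stats, function(tb) {
            fo <- topFraction(tb$fst, rownames(tb), cfg$fstFraction)
            dxo <- topFraction(tb$dxy, rownames(tb), cfg$dxyFraction)
            list(fst = fo, dxy = dxo, ogd = callOGD(fo, dxo))
        })
        names(out) <- pairName
        out
    })
    # --- association --------------------------------------------------
    assoc <- stage("associate", {
        out <- list()
        for (p in pops) {
            prIdx <- which(vapply(pairs, function(pr) p %in% pr, logical(1)))
            defined <- lapply(prIdx, function(i)
                rownames(stats[[i]])[!is.na(stats[[i]]$fst)])
            universe <- Reduce(intersect, defined)
            ogdP <- intersect(unique(unlist(
                lapply(prIdx, function(i) outl[[i]]$ogd))), universe)
            swP <- intersect(sweepWin[[p]], universe)
            out[[p]] <- ogdSweepAssociation(
                universe, ogdP, swP, reps = cfg$assocReps,
                seed = .splitSeed(cfg$seed, paste0("assoc", p)))
            attr(out[[p]], "ogd") <- ogdP
            attr(out[[p]], "sweepWindows") <- swP
        }
        out
    })
    # --- enrichment ---------------------------------------------------
    enrich <- stage("enrich", {
        if (is.null(dat$genes)) return(NULL)
        out <- list()
        for (p in pops) {
            ogdP <- attr(assoc[[p]], "ogd")
            swP <- attr(assoc[[p]], "sweepWindows")
            targetWin <- windows[intersect(ogdP, swP)]
            target <- genesInRegions(dat$genes, targetWin)
            fams <- setdiff(unique(dat$genes$family), "other")
            famTab <- do.call(rbind, lapply(fams, function(f)
                familyEnrichment(dat$genes, target, f)))
            go <- goOverrepresentation(dat$genes, target,
                                       fdrThreshold = cfg$fdr)
            out[[p]] <- list(targetGenes = target, family = famTab, go = go)
        }
        out
    })
    pca <- stage("pca", tryCatch(pcaQuicklook(vt), error = function(e) NULL))
    counts <- list(
        n_sites_input = nInput, n_sites_used = nrow(vt),
        n_windows = length(windows),
        fst_outliers = vapply(outl, function(x) length(x$fst), integer(1)),
        dxy_outliers = vapply(outl, function(x) length(x$dxy), integer(1)),
        ogd = vapply(outl, function(x) length(x$ogd), integer(1)),
        sweep_loci = vapply(sweepLoci, nrow, integer(1)),
        sweep_windows = vapply(sweepWin, length, integer(1)),
        ogd_sweep_overlap = vapply(pops, function(p)
            as.integer(assoc[[p]]@observed), integer(1)),
        association_p = vapply(pops, function(p) assoc[[p]]@p, numeric(1)),
        genome_fst = vapply(stats, function(tb) attr(tb, "genome_fst"),
                            numeric(1)),
        fst_perm_p = vapply(fstPerm, permPvalue, numeric(1)),
        kendall_tau = vapply(kendall, function(x) x$tau, numeric(1)))
    report <- list(config = cfg, counts = counts, stats = stats,
                   kendall = kendall, fstPermutation = fstPerm,
                   scans = scans, sweepLoci = sweepLoci,
                   sweepWindows = sweepWin, outliers = outl,
                   association = assoc, enrichment = enrich, pca = pca,
                   genes = dat$genes, windows = windows, vt = vt, pm = pm)
    if (!is.null(cfg$outDir)) .writeReport(report, cfg$outDir)
    report
}

# Write the report's result tables (tab-separated + BED) to a directory.
.writeReport <- function(report, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report$stats))
        writeStatsTable(report$stats[[nm]],
                        file.path(outDir, paste0("window_stats_", nm, ".tsv")))
    for (nm in names(report$scans))
        writeStatsTable(scanTable(report$scans[[nm]]),
                        file.path(outDir, paste0("sweep_scan_", nm, ".tsv")))
    for (nm in names(report$sweepLoci)) {
        loci <- report$sweepLoci[[nm]]
        if (nrow(loci))
            writeBED(loci, file.path(outDir,
                                     paste0("sweep_loci_", nm, ".bed")))
    }
    calls <- do.call(rbind, lapply(names(report$outliers), function(nm) {
        o <- report$outliers[[nm]]
        ids <- rownames(report$stats[[nm]])
        data.frame(pair = nm, window = ids,
                   fst_outlier = ids %in% o$fst,
                   dxy_outlier = ids %in% o$dxy,
                   ogd = ids %in% o$ogd, stringsAsFactors = FALSE)
    }))
    writeStatsTable(calls, file.path(outDir, "outlier_calls.tsv"))
    perm <- data.frame(
        test = c(paste0("fst_perm_", names(report$fstPermutation)),
                 paste0("assoc_", names(report$association))),
        observed = c(vapply(report$fstPermutation, function(x) x@observed,
                            numeric(1)),
                     vapply(report$association, function(x) x@observed,
                            numeric(1))),
        p = c(vapply(report$fstPermutation, permPvalue, numeric(1)),
              vapply(report$association, permPvalue, numeric(1))),
        seed = c(vapply(report$fstPermutation, function(x) x@seed,
                        integer(1)),
                 vapply(report$association, function(x) x@seed, integer(1))))
    writeStatsTable(perm, file.path(outDir, "permutation_tests.tsv"))
    if (!is.null(report$enrichment))
        for (nm in names(report$enrichment)) {
            e <- report$enrichment[[nm]]
            writeStatsTable(e$family,
                            file.path(outDir,
                                      paste0("enrichment_family_", nm,
                                             ".tsv")))
            if (nrow(e$go))
                writeStatsTable(e$go,
                                file.path(outDir,
                                          paste0("enrichment_go_", nm,
                                                 ".tsv")))
        }
    cfg <- report$config
    cfg$scenario <- NULL
    cfg$outDir <- NULL
    yaml::write_yaml(c(cfg, list(counts = lapply(report$counts, unname))),
                     file.path(outDir, "report.yaml"))
    invisible(NULL)
}
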