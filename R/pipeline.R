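#' @include simulate.R
NULL

#' Assemble and validate a run configuration
#'
#' A run configuration names the three plate input files (vectors for
#' multi-plate experiments), the QC, normalization, differential and
#' functional settings, the output directory and the seed. `runConfig()`
#' builds one from arguments; [readRunConfig()] loads the same structure
#' from a YAML file (flag-style arguments to [runPipeline()] override file
#' values). All referenced files must exist at validation time.
#'
#' @param counts character vector of Ct table paths, one per plate.
#' @param annotation well annotation path(s); recycled across plates.
#' @param metadata sample sheet path.
#' @param outputDir directory for the result tree.
#' @param maxNaFraction,rtThreshold,rtForm QC settings (see [applyQC()]).
#' @param normalization `"endogenous"` or `"exogenous"`.
#' @param controls optional control-assay override (see [referenceCt()]).
#' @param contrast character pair `c(test, reference)`; defaults to the two
#'   groups in the sample sheet (second level as reference) when `NULL`.
#' @param alpha adjusted-p threshold for significance.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @param targets optional target-table TSV path; functional analysis is
#'   skipped when absent.
#' @param geneSets optional character vector of GMT paths.
#' @param evidence,minSources target filters (see [targetsFor()]).
#' @param seed integer seed echoed into the report (the pipeline itself is
#'   deterministic; the seed matters when the config is used to simulate).
#' @return validated config (list, class `runConfig`).
#' @export
runConfig <- function(counts, annotation, metadata, outputDir,
                      maxNaFraction = 0.10, rtThreshold = 5,
                      rtForm = "difference",
                      normalization = "endogenous", controls = NULL,
                      contrast = NULL, alpha = 0.05, adjust = "BH",
                      targets = NULL, geneSets = NULL,
                      evidence = "both", minSources = 1, seed = 1) {
    cfg <- list(counts = counts, annotation = annotation,
                metadata = metadata, outputDir = outputDir,
                maxNaFraction = maxNaFraction, rtThreshold = rtThreshold,
                rtForm = rtForm, normalization = normalization,
                controls = controls, contrast = contrast, alpha = alpha,
                adjust = adjust, targets = targets, geneSets = geneSets,
                evidence = evidence, minSources = minSources,
                seed = as.integer(seed))
    class(cfg) <- "runConfig"
    validateRunConfig(cfg)
}

#' @rdname runConfig
#' @param path YAML file whose top-level keys are the `runConfig()`
#'   argument names.
#' @param ... overrides applied on top of the file values (the flag side of
#'   the flags-over-file convention).
#' @export
readRunConfig <- function(path, ...) {
    y <- yaml::read_yaml(path)
    over <- list(...)
    y[names(over)] <- over
    known <- names(formals(runConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    do.call(runConfig, y)
}

validateRunConfig <- function(cfg) {
    stopifnot(inherits(cfg, "runConfig"))
    files <- c(cfg$counts, cfg$annotation, cfg$metadata, cfg$targets,
               cfg$geneSets)
    missing <- files[!file.exists(files)]
    if (length(missing))
        stop("config references missing file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    stopifnot(cfg$maxNaFraction >= 0, cfg$maxNaFraction <= 1,
              cfg$rtThreshold > 0, cfg$alpha > 0, cfg$alpha <= 1,
              cfg$minSources >= 1,
              cfg$normalization %in% c("endogenous", "exogenous"),
              cfg$adjust %in% c("BH", "bonferroni"),
              cfg$evidence %in% c("both", "validated", "predicted"),
              is.null(cfg$contrast) || length(cfg$contrast) == 2L)
    cfg
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the three phases end to end — (1) input parsing, sample QC and
#' delta-Ct normalization, (2) moderated-t differential expression with
#' hierarchical clustering, (3) target mapping and over-representation
#' analysis — and writes a result tree under the configured output
#' directory:
#'
#' \preformatted{
#'   qc/          qc_report.csv, na_overlap.csv
#'   normalized/  normalized_matrix.tsv, boxplot_data.csv
#'   de/          de_table.tsv, dropped_mirnas.txt
#'   functional/  target_genes.tsv, enrichment_<collection>.tsv
#'   figures/     boxplots, NA upset data, heatmap, enrichment barplot
#'   report.md, report.json
#' }
#'
#' Stages short-circuit cleanly: with no significant miRNAs the heatmap and
#' the functional phase are skipped and the report says so. Stage failures
#' propagate as errors prefixed with the stage name; outputs written before
#' the failure are kept. Given the same inputs the emitted tables are
#' byte-identical across runs.
#'
#' @param config a `runConfig` (or path to a YAML accepted by
#'   [readRunConfig()]).
#' @param figures render PNG figures (default `TRUE`); plot-data tables are
#'   written regardless.
#' @return (invisibly) the output directory; the run report is written to
#'   `report.json` / `report.md` there (see [writeRunReport()]).
#' @examples
#' indir <- tempfile(); outdir <- tempfile()
#' sim <- simulatePlates(simulationScenario(seed = 42))
#' paths <- writeSimulatedInputs(sim, indir)
#' cfg <- runConfig(counts = paths[["counts"]],
#'                  annotation = paths[["annotation"]],
#'                  metadata = paths[["metadata"]],
#'                  outputDir = outdir)
#' runPipeline(cfg, figures = FALSE)
#' list.files(outdir, recursive = TRUE)
#' @name runPipeline
#' @export
runPipeline <- function(config, figures = TRUE) {
    if (is.character(config))
        config <- readRunConfig(config)
    config <- validateRunConfig(config)
    t0 <- proc.time()[["elapsed"]]
    gc(reset = TRUE)
    out <- config$outputDir
    for (d in c("", "qc", "normalized", "de", "functional", "figures"))
        dir.create(file.path(out, d), showWarnings = FALSE,
                   recursive = TRUE)
    notes <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }

    ## ---- phase 1: input, QC, normalization -------------------------------
    exper <- stage("input", {
        anns <- rep_len(config$annotation, length(config$counts))
        plates <- lapply(seq_along(config$counts), function(i) {
            layout <- readWellAnnotation(anns[[i]],
                                         plateId = paste0("plate", i))
            ct <- readCtTable(config$counts[[i]])
            CtExperiment(ct, layout)
        })
        merged <- mergePlates(plates)
        sheet <- readSampleSheet(config$metadata,
                                 samples = colnames(merged))
        colData(merged)$group <- sheet$group[match(colnames(merged),
                                                   sheet$sample)]
        merged
    })
    qc <- stage("quality_control", applyQC(
        exper, maxNaFraction = config$maxNaFraction,
        rtThreshold = config$rtThreshold, rtForm = config$rtForm))
    utils::write.csv(qc$report, file.path(out, "qc", "qc_report.csv"),
                     row.names = FALSE)
    overlap <- naOverlapSummary(exper)
    utils::write.csv(overlap, file.path(out, "qc", "na_overlap.csv"),
                     row.names = FALSE)
    nse <- stage("normalization", normalizeCt(
        qc$experiment, mode = config$normalization,
        controls = config$controls))
    nm <- assay(nse, "negDeltaCt")
    .writeTsv(data.frame(mirna = rownames(nm), nm, check.names = FALSE),
              file.path(out, "normalized", "normalized_matrix.tsv"))
    boxdata <- data.frame(
        sample = rep(colnames(nse), each = 2L),
        stage = rep(c("raw_ct", "neg_delta_ct"), times = ncol(nse)),
        median = as.vector(rbind(
            apply(ctValues(qc$experiment), 2L, stats::median, na.rm = TRUE),
            apply(nm, 2L, stats::median, na.rm = TRUE))))
    utils::write.csv(boxdata, file.path(out, "normalized",
                                        "boxplot_data.csv"),
                     row.names = FALSE)

    ## ---- phase 2: differential analysis ----------------------------------
    grp <- sampleGroups(nse)
    contrast <- config$contrast
    if (is.null(contrast)) {
        lv <- unique(grp[!is.na(grp)])
        if (length(lv) != 2L)
            stop("[differential] contrast required: samples have ",
                 length(lv), " groups", call. = FALSE)
        contrast <- c(lv[2L], lv[1L])
    }
    de <- stage("differential", differentialExpression(
        nse, contrast = contrast, alpha = config$alpha,
        adjust = config$adjust))
    .writeTsv(de, file.path(out, "de", "de_table.tsv"))
    writeLines(attr(de, "dropped"),
               file.path(out, "de", "dropped_mirnas.txt"))
    clus <- clusterSignificant(nse, de)
    if (is.null(clus))
        notes <- c(notes, "heatmap skipped: fewer than 2 significant miRNAs")
    else
        utils::write.csv(
            data.frame(mirna = rownames(clus$matrix), clus$matrix,
                       check.names = FALSE),
            file.path(out, "de", "heatmap_matrix.csv"), row.names = FALSE)

    ## ---- phase 3: functional analysis ------------------------------------
    nsig <- sum(de$significant)
    sigMirnas <- de$mirna[de$significant]
    targetHits <- NULL
    enrichments <- list()
    if (is.null(config$targets)) {
        notes <- c(notes, "functional analysis skipped: no target table")
    } else if (nsig == 0L) {
        notes <- c(notes,
                   "functional analysis skipped: no significant miRNAs")
    } else {
        ttab <- stage("functional", loadTargetTable(config$targets))
        targetHits <- stage("functional", targetsFor(
            sigMirnas, ttab, evidence = config$evidence,
            minSources = config$minSources))
        .writeTsv(targetHits,
                  file.path(out, "functional", "target_genes.tsv"))
        if (nrow(targetHits) && length(config$geneSets)) {
            for (gmt in config$geneSets) {
                coll <- stage("functional", loadGmt(gmt))
                uni <- intersect(unique(unlist(coll, use.names = FALSE)),
                                 unique(ttab$gene))
                er <- stage("functional", enrich(
                    targetHits$gene, coll, universe = uni))
                nm2 <- tools::file_path_sans_ext(basename(gmt))
                enrichments[[nm2]] <- er
                .writeTsv(er, file.path(
                    out, "functional",
                    paste0("enrichment_", nm2, ".tsv")))
            }
        } else if (!nrow(targetHits)) {
            notes <- c(notes, "enrichment skipped: no target genes mapped")
        }
    }

    if (figures)
        .renderFigures(out, qc, overlap, nse, clus, enrichments)

    ## ---- report -----------------------------------------------------------
    elapsed <- proc.time()[["elapsed"]] - t0
    gcinfo <- gc()
    peakMb <- sum(gcinfo[, ncol(gcinfo)])   # max-used (Mb) column, Ncells+Vcells
    report <- list(
        tool = "miRct", version = as.character(utils::packageVersion("miRct")),
        timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
        parameters = unclass(config),
        qc = list(
            samplesIn = nrow(qc$report),
            samplesRetained = sum(!qc$report$excluded),
            excluded = if (any(qc$report$excluded))
                lapply(which(qc$report$excluded), function(i)
                    list(sample = qc$report$sample[i],
                         reason = qc$report$reason[i]))
            else list()),
        counts = list(
            wells = nrow(exper), plates = length(config$counts),
            mirnasTested = nrow(de),
            mirnasDropped = length(attr(de, "dropped")),
            significant = nsig,
            targetGenes = if (is.null(targetHits)) NA_integer_
                          else nrow(targetHits),
            geneSetCollections = length(enrichments),
            setsTested = vapply(enrichments, nrow, integer(1))),
        contrast = contrast,
        notes = notes,
        elapsedSeconds = round(elapsed, 3),
        peakMemoryMb = round(unname(peakMb), 1))
    writeRunReport(report, file.path(out, "report"))
    invisible(out)
}

.renderFigures <- function(out, qc, overlap, nse, clus, enrichments) {
    fig <- function(name, w = 800, h = 600, code) {
        grDevices::png(file.path(out, "figures", name), width = w,
                       height = h)
        on.exit(grDevices::dev.off())
        code
    }
    nm <- assay(nse, "negDeltaCt")
    fig("boxplot_before.png", code = graphics::boxplot(
        ctValues(qc$experiment), las = 2, ylab = "raw Ct (cycles)",
        main = "Before normalization"))
    fig("boxplot_after.png", code = graphics::boxplot(
        nm, las = 2, ylab = expression(-Delta * "Ct (log2)"),
        main = "After normalization"))
    if (nrow(overlap))
        fig("na_upset.png", code = graphics::barplot(
            overlap$count, names.arg = overlap$samples, las = 2,
            ylab = "miRNAs missing in exactly this sample set",
            main = "Not-detected overlap"))
    if (!is.null(clus))
        fig("heatmap.png", code = print(pheatmap::pheatmap(
            clus$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
            main = "Significant miRNAs (row z-scores)", silent = TRUE)))
    for (nm2 in names(enrichments)) {
        er <- utils::head(enrichments[[nm2]], 15L)
        if (!nrow(er)) next
        fig(paste0("enrichment_", nm2, ".png"), code = {
            graphics::par(mar = c(5, 12, 4, 2))
            graphics::barplot(rev(-log10(er$pValue)),
                              names.arg = rev(er$set), horiz = TRUE,
                              las = 1, xlab = "-log10 p",
                              main = paste("Enrichment:", nm2))
        })
    }
    invisible(NULL)
}
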