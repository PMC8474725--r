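#' @include pipeline.R
NULL

#' Write the automated run report
#'
#' Serializes a run report twice: a human-readable Markdown file
#' (`<stem>.md`) and a machine-readable JSON twin (`<stem>.json`) holding
#' the identical structure. The report echoes the user-defined criteria,
#' lists every excluded sample with its reason, records the counts at each
#' stage, and states the wall-clock duration and peak memory of the run.
#'
#' @param report named list as assembled by [runPipeline()]: `tool`,
#'   `version`, `timestamp`, `parameters`, `qc` (with `samplesIn`,
#'   `samplesRetained`, `excluded`), `counts`, `contrast`, `notes`,
#'   `elapsedSeconds`, `peakMemoryMb`.
#' @param stem output path without extension.
#' @return (invisibly) character vector of the two written paths.
#' @export
writeRunReport <- function(report, stem) {
    jsonPath <- paste0(stem, ".json")
    mdPath <- paste0(stem, ".md")
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    excl <- report$qc$excluded
    exclTxt <- if (length(excl))
        vapply(excl, function(e)
            sprintf("- `%s`: %s", e$sample, e$reason), character(1))
    else "- none excluded"
    par <- report$parameters
    parTxt <- vapply(names(par), function(k) {
        v <- par[[k]]
        sprintf("- %s: %s", k,
                if (is.null(v)) "(default)" else
                    paste(as.character(v), collapse = ", "))
    }, character(1))
    cnt <- report$counts
    md <- c(
        sprintf("# %s run report (v%s)", report$tool, report$version),
        "", sprintf("Generated: %s", report$timestamp), "",
        "## Parameters", parTxt, "",
        "## Sample quality control",
        sprintf("- samples in: %d", report$qc$samplesIn),
        sprintf("- samples retained: %d", report$qc$samplesRetained),
        "### Excluded samples", exclTxt, "",
        "## Stage counts",
        sprintf("- wells: %d (plates: %d)", cnt$wells, cnt$plates),
        sprintf("- miRNAs tested: %d (dropped: %d)", cnt$mirnasTested,
                cnt$mirnasDropped),
        sprintf("- significant miRNAs (contrast %s vs %s): %d",
                report$contrast[1L], report$contrast[2L], cnt$significant),
        sprintf("- target genes mapped: %s",
                ifelse(is.na(cnt$targetGenes), "not run",
                       cnt$targetGenes)),
        sprintf("- gene-set collections tested: %d",
                cnt$geneSetCollections),
        "", "## Notes",
        if (length(report$notes)) paste0("- ", report$notes) else "- none",
        "", "## Resources",
        sprintf("- elapsed: %.3f s", report$elapsedSeconds),
        sprintf("- peak memory: %.1f MB", report$peakMemoryMb))
    writeLines(md, mdPath)
    invisible(c(markdown = mdPath, json = jsonPath))
}

#' Read the JSON twin of a run report
#'
#' @param path path to a `report.json` written by [writeRunReport()].
#' @return the report as a named list.
#' @export
readRunReport <- function(path) {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}
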