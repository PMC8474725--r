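#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData colData<-
NULL

## Recognised well roles on a miScript-style array plate.
.WELL_ROLES <- c("MIRNA", "CE_SPIKE", "SNORNA_SNRNA", "RTC", "PPC")

## Default control assay panels (vendor names; matching is case-insensitive).
.ENDOGENOUS_ASSAYS <- c("SNORD61", "SNORD68", "SNORD72", "SNORD95",
                        "SNORD96A", "RNU6B")
.EXOGENOUS_ASSAYS <- "cel-miR-39"

#' Container for raw Ct plate data
#'
#' `CtExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one or more 384-well plates of raw threshold-cycle (Ct) values:
#' wells on rows, samples on columns. The single assay, `"ct"`, stores Ct
#' in PCR cycles with `NA` marking wells reported as not detected.
#' `rowData` carries the well annotation (`plate`, `well`, `assay`, `role`);
#' `colData` carries the sample `group` labels.
#'
#' Roles partition the wells into miRNA assays (`MIRNA`) and the four control
#' classes: cel-miR-39 spike-ins (`CE_SPIKE`), snoRNA/snRNA endogenous
#' controls (`SNORNA_SNRNA`), reverse-transcription controls (`RTC`) and
#' positive PCR controls (`PPC`).
#'
#' @seealso [CtExperiment()] for construction from parsed inputs,
#'   [readCtTable()], [readWellAnnotation()], [readSampleSheet()].
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
    msg <- character()
    if (!("ct" %in% assayNames(object)))
        msg <- c(msg, "assay 'ct' is required")
    rd <- rowData(object)
    need <- c("plate", "well", "assay", "role")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss)) {
        bad <- setdiff(unique(rd$role), .WELL_ROLES)
        if (length(bad))
            msg <- c(msg, paste0("unknown well role(s): ",
                                 paste(bad, collapse = ", ")))
        key <- paste(rd$plate, rd$well, sep = ":")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (plate, well) keys")
        if (any(!nzchar(as.character(rd$assay))))
            msg <- c(msg, "empty assay ids")
    }
    if (!("group" %in% colnames(colData(object))))
        msg <- c(msg, "colData lacks column 'group'")
    if ("ct" %in% assayNames(object)) {
        v <- assay(object, "ct")
        if (any(is.infinite(v)))
            msg <- c(msg, "Ct values must be finite or NA")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Container for normalized miRNA expression
#'
#' `NormalizedCtExperiment` holds the \eqn{-\Delta Ct} matrix (log2 relative
#' expression) produced by [normalizeCt()]: miRNA assays on rows, retained
#' samples on columns, assay name `"negDeltaCt"`. `colData` keeps the sample
#' `group` and the per-sample `referenceCt` (mean control Ct, in cycles) the
#' normalization subtracted from. `metadata(x)$controlsUsed` records which
#' control assays were available per sample.
#'
#' @seealso [normalizeCt()], [relativeExpression()], [sampleReference()]
#' @export
setClass("NormalizedCtExperiment", contains = "SummarizedExperiment")

setValidity("NormalizedCtExperiment", function(object) {
    msg <- character()
    if (!("negDeltaCt" %in% assayNames(object)))
        msg <- c(msg, "assay 'negDeltaCt' is required")
    cd <- colData(object)
    if (!all(c("group", "referenceCt") %in% colnames(cd)))
        msg <- c(msg, "colData needs 'group' and 'referenceCt'")
    else if (any(!is.finite(cd$referenceCt)))
        msg <- c(msg, "referenceCt must be finite")
    if (length(msg)) msg else TRUE
})
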