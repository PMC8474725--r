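#' @include qc.R
NULL

## case-insensitive, whitespace-trimmed assay matching
.foldAssay <- function(a) tolower(trimws(a))

#' Collapse replicate wells to one row per assay
#'
#' Assays spotted in several wells (within or across plates) are combined by
#' taking the arithmetic mean of their non-missing Ct values per sample; the
#' result is missing only where every replicate well is missing.
#'
#' @param x a [CtExperiment-class]
#' @return [SummarizedExperiment::SummarizedExperiment] with one row per
#'   assay (assay `"ct"`, rowData `assay` and `role`, colData preserved).
#' @export
collapseReplicates <- function(x) {
    ct <- ctValues(x)
    aid <- as.character(rowData(x)$assay)
    role <- as.character(rowData(x)$role)
    grp <- factor(aid, levels = unique(aid))
    n_obs <- rowsum((!is.na(ct)) + 0L, grp)
    total <- rowsum(replace(ct, is.na(ct), 0), grp)
    val <- total / n_obs           # NaN where no replicate observed
    val[n_obs == 0L] <- NA_real_
    rrole <- vapply(split(role, grp), function(r) r[1L], character(1))
    SummarizedExperiment(
        assays = list(ct = as.matrix(val)),
        rowData = DataFrame(assay = levels(grp), role = unname(rrole),
                            row.names = levels(grp)),
        colData = colData(x))
}

#' Per-sample reference Ct from control assays
#'
#' The arithmetic mean Ct of the selected control assays observed in each
#' sample (a geometric mean on the linear scale). In endogenous mode the
#' default panel is the five snoRNAs SNORD61/68/72/95/96A plus the snRNA
#' RNU6B; in exogenous mode the cel-miR-39 spike-in, the usual choice for
#' biofluid samples. Control assays missing in a sample are dropped from
#' that sample's mean (dropout of single controls is common); a sample in
#' which every selected control is missing is an error.
#'
#' @param collapsed assay-level experiment from [collapseReplicates()].
#' @param mode `"endogenous"` or `"exogenous"`.
#' @param controls optional explicit control assay names overriding the
#'   default panel for the mode; matched case-insensitively.
#' @return named numeric vector of reference Ct per sample, with attribute
#'   `controlsUsed`: a per-sample list of the control assays averaged.
#' @export
referenceCt <- function(collapsed, mode = c("endogenous", "exogenous"),
                        controls = NULL) {
    mode <- match.arg(mode)
    if (is.null(controls))
        controls <- if (mode == "endogenous") .ENDOGENOUS_ASSAYS
                    else .EXOGENOUS_ASSAYS
    stopifnot(length(controls) >= 1L)
    aid <- as.character(rowData(collapsed)$assay)
    hit <- .foldAssay(aid) %in% .foldAssay(controls)
    if (!any(hit))
        stop("none of the control assays (",
             paste(controls, collapse = ", "),
             ") are present in the layout", call. = FALSE)
    ct <- assay(collapsed, "ct")[hit, , drop = FALSE]
    ref <- colMeans(ct, na.rm = TRUE)
    dead <- !is.finite(ref)
    if (any(dead))
        stop("all selected control assays missing in sample(s): ",
             paste(colnames(ct)[dead], collapse = ", "), call. = FALSE)
    used <- apply(ct, 2L, function(v) aid[hit][!is.na(v)], simplify = FALSE)
    attr(ref, "controlsUsed") <- used
    ref
}

#' Delta-Ct normalization to a per-sample reference
#'
#' Subtracts each miRNA's Ct from the sample's reference Ct, yielding
#' \eqn{-\Delta Ct = Ct_{ref} - Ct_{miRNA}}: log2 relative expression with
#' the conventional orientation (larger value = more abundant, one unit =
#' one PCR cycle = 2-fold). Only `MIRNA` rows are kept; control rows served
#' their purpose in the reference. The not-detected mask propagates.
#'
#' @param collapsed assay-level experiment from [collapseReplicates()].
#' @param reference named per-sample reference Ct, as from [referenceCt()].
#' @return a [NormalizedCtExperiment-class]
#' @export
deltaCtNormalize <- function(collapsed, reference) {
    stopifnot(all(colnames(collapsed) %in% names(reference)))
    reference <- reference[colnames(collapsed)]
    keep <- as.character(rowData(collapsed)$role) == "MIRNA"
    ct <- assay(collapsed, "ct")[keep, , drop = FALSE]
    nd <- sweep(-ct, 2L, reference, "+")
    cd <- colData(collapsed)
    cd$referenceCt <- unname(reference)
    se <- SummarizedExperiment(assays = list(negDeltaCt = nd),
                               rowData = rowData(collapsed)[keep, ,
                                                            drop = FALSE],
                               colData = cd)
    out <- new("NormalizedCtExperiment", se)
    cu <- attr(reference, "controlsUsed")
    if (!is.null(cu))
        metadata(out)$controlsUsed <- cu
    out
}

#' Normalize a Ct experiment in one call
#'
#' Convenience wrapper: [collapseReplicates()], then [referenceCt()], then
#' [deltaCtNormalize()].
#'
#' @inheritParams referenceCt
#' @param x a [CtExperiment-class] (typically the QC-filtered one).
#' @return a [NormalizedCtExperiment-class]
#' @examples
#' sim <- simulatePlates(simulationScenario(seed = 3))
#' nse <- normalizeCt(applyQC(sim$experiment)$experiment)
#' nse
#' @export
normalizeCt <- function(x, mode = c("endogenous", "exogenous"),
                        controls = NULL) {
    collapsed <- collapseReplicates(x)
    ref <- referenceCt(collapsed, mode = mode, controls = controls)
    deltaCtNormalize(collapsed, ref)
}

#' Linear-scale relative expression
#'
#' Elementwise \eqn{2^{-\Delta Ct}}; strictly positive wherever observed.
#'
#' @param x a [NormalizedCtExperiment-class]
#' @return numeric matrix on the linear relative-quantity scale.
#' @export
relativeExpression <- function(x) {
    stopifnot(is(x, "NormalizedCtExperiment"))
    2^assay(x, "negDeltaCt")
}
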