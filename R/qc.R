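#' @include plate-io.R
NULL

#' Per-sample fraction of not-detected wells
#'
#' Fraction of masked (not detected) cells per sample, by default over the
#' miRNA wells only: control dropout is judged by the RT-efficiency check
#' instead, so it is not double-counted here.
#'
#' @param x a [CtExperiment-class]
#' @param mirnaOnly count over `MIRNA` wells only (default `TRUE`) or over
#'   all wells.
#' @return named numeric vector in `[0, 1]`, one value per sample.
#' @export
naFraction <- function(x, mirnaOnly = TRUE) {
    m <- missingMask(x)
    if (mirnaOnly)
        m <- m[wellRoles(x) == "MIRNA", , drop = FALSE]
    if (nrow(m) == 0L)
        stop("no wells to compute the NA fraction over", call. = FALSE)
    colMeans(m)
}

#' Reverse-transcription efficiency statistic
#'
#' Per sample, the mean Ct of the reverse-transcription control (RTC) wells
#' minus the mean Ct of the positive PCR control (PPC) wells, in cycles. The
#' RTC assay detects an artificial RNA template (so it reflects RT
#' efficiency) while the PPC monitors PCR inhibition; their difference
#' isolates reverse-transcription failure. A sample passes when the
#' statistic is below the threshold (default 5 cycles, see [applyQC()]).
#' `form = "quotient"` instead returns mean(RTC)/mean(PPC) for users whose
#' vendor criterion is a literal ratio.
#'
#' Samples whose RTC or PPC wells are all missing get `NA` (QC then fails
#' them with reason "controls missing").
#'
#' @param x a [CtExperiment-class]
#' @param form `"difference"` (default) or `"quotient"`.
#' @return named numeric vector, one statistic per sample (`NA` when the
#'   controls are unusable).
#' @export
rtStatistic <- function(x, form = c("difference", "quotient")) {
    form <- match.arg(form)
    ct <- ctValues(x)
    role <- wellRoles(x)
    rtc <- ct[role == "RTC", , drop = FALSE]
    ppc <- ct[role == "PPC", , drop = FALSE]
    if (nrow(rtc) == 0L || nrow(ppc) == 0L)
        stop("layout has no RTC or no PPC wells; RT check impossible",
             call. = FALSE)
    mrtc <- colMeans(rtc, na.rm = TRUE)
    mppc <- colMeans(ppc, na.rm = TRUE)
    out <- if (form == "difference") mrtc - mppc else mrtc / mppc
    out[!is.finite(out)] <- NA_real_
    out
}

#' Sample quality control
#'
#' Applies the two sample-level checks in order: (1) the fraction of
#' not-detected miRNA wells must not exceed `maxNaFraction`; (2) the
#' RT-efficiency statistic ([rtStatistic()]) must be below `rtThreshold`
#' (default 5, the printed vendor rule). Both statistics are recorded for
#' every sample regardless of the outcome; failing samples are excluded from
#' the returned experiment with a reason.
#'
#' @param x a [CtExperiment-class]
#' @param maxNaFraction maximum tolerated NA fraction in `[0, 1]`
#'   (default 0.10, the case-study setting).
#' @param rtThreshold RT pass threshold in cycles (default 5).
#' @param rtForm statistic form passed to [rtStatistic()].
#' @param mirnaOnly denominator choice passed to [naFraction()].
#' @return list with `experiment` (the filtered [CtExperiment-class]) and
#'   `report` (data.frame: sample, group, naFraction, rtStatistic, naPass,
#'   rtPass, excluded, reason). Errors if every sample is excluded; the
#'   report is attached to the condition as `condition$report`.
#' @examples
#' sim <- simulatePlates(simulationScenario(seed = 7))
#' qc <- applyQC(sim$experiment)
#' qc$report
#' @export
applyQC <- function(x, maxNaFraction = 0.10, rtThreshold = 5,
                    rtForm = c("difference", "quotient"), mirnaOnly = TRUE) {
    stopifnot(maxNaFraction >= 0, maxNaFraction <= 1, rtThreshold > 0)
    rtForm <- match.arg(rtForm)
    if (ncol(x) == 0L)
        stop("no samples in experiment", call. = FALSE)
    naf <- naFraction(x, mirnaOnly = mirnaOnly)
    rts <- rtStatistic(x, form = rtForm)
    naPass <- naf <= maxNaFraction
    rtPass <- !is.na(rts) & rts < rtThreshold
    reason <- rep("", ncol(x))
    reason[!naPass] <- "NA fraction"
    reason[naPass & is.na(rts)] <- "controls missing"
    reason[naPass & !is.na(rts) & !rtPass] <- "RT efficiency"
    excluded <- !(naPass & rtPass)
    report <- data.frame(
        sample = colnames(x), group = sampleGroups(x),
        naFraction = unname(naf), rtStatistic = unname(rts),
        naPass = unname(naPass), rtPass = unname(rtPass),
        excluded = unname(excluded), reason = reason,
        stringsAsFactors = FALSE, row.names = NULL)
    if (all(excluded)) {
        cond <- simpleError("all samples excluded by quality control")
        cond$report <- report
        stop(cond)
    }
    list(experiment = x[, !excluded], report = report)
}

#' Exclusive intersections of per-sample missing miRNA sets
#'
#' Computes, for every subset of samples with a non-zero exclusive
#' intersection, how many miRNA assays are missing in exactly those samples
#' — the numbers behind an upset plot of the NA structure. A miRNA counts as
#' missing in a sample when all its wells are masked there. Counts sum to
#' the number of miRNAs missing in at least one sample.
#'
#' @param x a [CtExperiment-class]
#' @return data.frame with columns `samples` (ids joined by `"&"`), `count`,
#'   sorted by decreasing count; zero rows when nothing is missing.
#' @export
naOverlapSummary <- function(x) {
    if (ncol(x) == 0L)
        stop("no samples in experiment", call. = FALSE)
    m <- missingMask(x)[wellRoles(x) == "MIRNA", , drop = FALSE]
    aid <- assayIds(x)[wellRoles(x) == "MIRNA"]
    ## a miRNA is missing iff all of its (possibly replicate) wells are
    miss <- rowsum(m + 0L, aid) == rowsum(matrix(1L, nrow(m), ncol(m)), aid)
    miss <- miss[rowSums(miss) > 0L, , drop = FALSE]
    if (nrow(miss) == 0L)
        return(data.frame(samples = character(), count = integer(),
                          stringsAsFactors = FALSE))
    pattern <- apply(miss, 1L, function(r)
        paste(colnames(miss)[r], collapse = "&"))
    tab <- table(pattern)
    out <- data.frame(samples = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$count, out$samples), , drop = FALSE]
}
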