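#' @include AllClasses.R
NULL

## Strings treated as "not detected" in vendor Ct exports. Vendors are not
## consistent; the set is a user-configurable argument everywhere it is used.
.DEFAULT_MISSING_MARKERS <- c("Undetermined", "N/A", "NA", "")

.detectDelim <- function(path) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L)
        stop("file '", path, "' is empty", call. = FALSE)
    if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

.readDelimChar <- function(path, delim = NULL) {
    if (is.null(delim))
        delim <- .detectDelim(path)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL, quote = "\"",
                            comment.char = "", fileEncoding = "UTF-8",
                            stringsAsFactors = FALSE)
    df[] <- lapply(df, trimws)
    names(df) <- trimws(names(df))
    df
}

#' Read a raw Ct count table
#'
#' Parses a delimited Ct table with well keys in the first column and one
#' column of Ct values per sample. Cells matching a missing-value marker
#' become `NA` (the not-detected mask); any other cell must parse as a
#' finite number. Ct values above `ctCeiling` cycles are additionally set
#' to `NA`, the usual qPCR practice for quantification limits.
#'
#' @param path file path; CSV or TSV (delimiter auto-detected unless given).
#' @param missingMarkers character vector of strings denoting not-detected
#'   wells. Default `c("Undetermined", "N/A", "NA", "")`.
#' @param ctCeiling Ct detection ceiling in cycles (default 35); use `Inf`
#'   to disable.
#' @param delim optional explicit field delimiter.
#' @return numeric matrix (wells x samples) with well keys as rownames and
#'   `NA` for not-detected cells.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("well,S1,S2", "A1,20.1,Undetermined", "A2,25.0,24.2"), tf)
#' readCtTable(tf)
#' @export
readCtTable <- function(path, missingMarkers = .DEFAULT_MISSING_MARKERS,
                        ctCeiling = 35, delim = NULL) {
    df <- .readDelimChar(path, delim)
    if (ncol(df) < 2L)
        stop("Ct table needs a well column plus at least one sample column",
             call. = FALSE)
    wells <- df[[1L]]
    dup <- wells[duplicated(wells)]
    if (length(dup))
        stop("duplicate well key(s) in Ct table: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample ids in Ct table header", call. = FALSE)
    mat <- matrix(NA_real_, nrow(df), length(samples),
                  dimnames = list(wells, samples))
    for (j in seq_along(samples)) {
        cell <- df[[j + 1L]]
        is_missing <- cell %in% missingMarkers
        val <- suppressWarnings(as.numeric(cell))
        bad <- !is_missing & (is.na(val) | !is.finite(val))
        if (any(bad)) {
            i <- which(bad)[1L]
            stop(sprintf(
                "cannot parse Ct value '%s' at well %s, sample %s",
                cell[i], wells[i], samples[j]), call. = FALSE)
        }
        val[is_missing] <- NA_real_
        mat[, j] <- val
    }
    mat[!is.na(mat) & mat > ctCeiling] <- NA_real_
    mat
}

.inferRole <- function(assay) {
    a <- tolower(trimws(assay))
    role <- rep("MIRNA", length(a))
    role[grepl("cel-mir-39", a, fixed = TRUE)] <- "CE_SPIKE"
    role[grepl("^snord", a) | grepl("^rnu6", a)] <- "SNORNA_SNRNA"
    role[grepl("mirtc", a, fixed = TRUE)] <- "RTC"
    role[grepl("^ppc", a)] <- "PPC"
    role
}

#' Read a well annotation table
#'
#' Reads the file linking each well position to its assay. Expected columns
#' are `well` (or `well_position`) and `assay` (or `assay_id`); `role` and
#' `plate` are optional. When `role` is absent it is inferred from the assay
#' name: cel-miR-39 wells become `CE_SPIKE`, SNORD*/RNU6* wells
#' `SNORNA_SNRNA`, miRTC wells `RTC`, PPC wells `PPC`, everything else
#' `MIRNA`. An explicit role column overrides the inference.
#'
#' @param path file path (CSV/TSV, header required).
#' @param plateId plate identifier used when the file has no `plate` column.
#' @param delim optional explicit delimiter.
#' @return [S4Vectors::DataFrame] with columns `plate`, `well`, `assay`,
#'   `role`.
#' @examples
#' layout <- readWellAnnotation(
#'   system.file("extdata", "standard_layout.csv", package = "miRct"))
#' summarizeLayout(layout)
#' @export
readWellAnnotation <- function(path, plateId = "plate1", delim = NULL) {
    df <- .readDelimChar(path, delim)
    names(df) <- tolower(names(df))
    wcol <- intersect(c("well", "well_position"), names(df))[1]
    acol <- intersect(c("assay", "assay_id", "mirna"), names(df))[1]
    if (is.na(wcol) || is.na(acol))
        stop("annotation needs columns 'well' (or 'well_position') and ",
             "'assay' (or 'assay_id')", call. = FALSE)
    well <- df[[wcol]]
    assay <- df[[acol]]
    if (any(!nzchar(assay)))
        stop("empty assay id in annotation row(s) ",
             paste(which(!nzchar(assay)), collapse = ", "), call. = FALSE)
    plate <- if ("plate" %in% names(df)) df[["plate"]] else
        if ("plate_id" %in% names(df)) df[["plate_id"]] else
        rep(plateId, nrow(df))
    key <- paste(plate, well, sep = ":")
    if (anyDuplicated(key))
        stop("duplicate (plate, well) in annotation: ",
             paste(unique(key[duplicated(key)]), collapse = ", "),
             call. = FALSE)
    if ("role" %in% names(df)) {
        role <- toupper(trimws(df[["role"]]))
        bad <- setdiff(unique(role), .WELL_ROLES)
        if (length(bad))
            stop("unknown role(s) in annotation: ",
                 paste(bad, collapse = ", "), "; expected one of ",
                 paste(.WELL_ROLES, collapse = ", "), call. = FALSE)
    } else {
        role <- .inferRole(assay)
    }
    DataFrame(plate = plate, well = well, assay = assay, role = role,
              row.names = key)
}

#' Read the sample sheet
#'
#' Two-column metadata file mapping sample id to group label (e.g.
#' normal/tumor). When `samples` is supplied, every one of those samples must
#' appear in the sheet; extra sheet rows are dropped with a warning.
#'
#' @param path file path (CSV/TSV with header).
#' @param samples optional character vector of sample ids that must be
#'   covered (typically `colnames` of the Ct table).
#' @param delim optional explicit delimiter.
#' @return data.frame with columns `sample`, `group`.
#' @export
readSampleSheet <- function(path, samples = NULL, delim = NULL) {
    df <- .readDelimChar(path, delim)
    if (ncol(df) < 2L)
        stop("sample sheet needs at least two columns (sample, group)",
             call. = FALSE)
    out <- data.frame(sample = df[[1L]], group = df[[2L]],
                      stringsAsFactors = FALSE)
    dup <- out$sample[duplicated(out$sample)]
    if (length(dup))
        stop("duplicate sample id(s) in sample sheet: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    if (!is.null(samples)) {
        miss <- setdiff(samples, out$sample)
        if (length(miss))
            stop("sample(s) in Ct table missing from sample sheet: ",
                 paste(miss, collapse = ", "), call. = FALSE)
        extra <- setdiff(out$sample, samples)
        if (length(extra)) {
            warning("dropping sample sheet row(s) not present in Ct table: ",
                    paste(extra, collapse = ", "), call. = FALSE)
            out <- out[out$sample %in% samples, , drop = FALSE]
        }
        out <- out[match(samples, out$sample), , drop = FALSE]
        rownames(out) <- NULL
    }
    out
}

#' Assemble a CtExperiment from parsed inputs
#'
#' Combines a raw Ct matrix, its well annotation and (optionally) the sample
#' sheet into a [CtExperiment-class]. Every Ct row must be annotated; layout
#' rows are matched by well key (`well` alone, or `plate:well` for merged
#' multi-plate matrices).
#'
#' @param ct numeric wells x samples matrix from [readCtTable()].
#' @param layout well annotation from [readWellAnnotation()].
#' @param samples optional sample sheet from [readSampleSheet()]; when absent
#'   group labels are `NA` (QC and normalization still work; differential
#'   analysis requires groups).
#' @return a [CtExperiment-class]
#' @export
CtExperiment <- function(ct, layout, samples = NULL) {
    stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
    key <- rownames(layout)
    idx <- match(rownames(ct), layout$well)
    if (anyNA(idx) || anyDuplicated(layout$well))
        idx <- match(rownames(ct), key)
    if (anyNA(idx))
        stop("Ct table well(s) missing from annotation: ",
             paste(rownames(ct)[is.na(idx)], collapse = ", "), call. = FALSE)
    layout <- layout[idx, , drop = FALSE]
    if (is.null(samples)) {
        cd <- DataFrame(group = rep(NA_character_, ncol(ct)),
                        row.names = colnames(ct))
    } else {
        samples <- readSampleSheetObject(samples, colnames(ct))
        cd <- DataFrame(group = samples$group, row.names = samples$sample)
    }
    rownames(ct) <- paste(layout$plate, layout$well, sep = ":")
    new("CtExperiment", SummarizedExperiment(
        assays = list(ct = ct),
        rowData = DataFrame(layout, row.names = rownames(ct)),
        colData = cd))
}

## accept either a path or an in-memory sheet
readSampleSheetObject <- function(samples, sampleIds) {
    if (is.character(samples) && length(samples) == 1L && file.exists(samples))
        return(readSampleSheet(samples, samples = sampleIds))
    stopifnot(is.data.frame(samples),
              all(c("sample", "group") %in% colnames(samples)))
    miss <- setdiff(sampleIds, samples$sample)
    if (length(miss))
        stop("sample(s) in Ct table missing from sample sheet: ",
             paste(miss, collapse = ", "), call. = FALSE)
    samples[match(sampleIds, samples$sample), c("sample", "group")]
}

#' Merge plates measured on the same samples
#'
#' Row-wise concatenation of several [CtExperiment-class] objects sharing the
#' same sample set, keyed by (plate, well). Assays appearing on several
#' plates keep all their wells; replicate wells are collapsed later by
#' [collapseReplicates()].
#'
#' @param ... `CtExperiment` objects, or a single list of them.
#' @return a single merged [CtExperiment-class].
#' @export
mergePlates <- function(...) {
    xs <- list(...)
    if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "CtExperiment"))
        xs <- xs[[1L]]
    stopifnot(length(xs) >= 1L,
              all(vapply(xs, is, logical(1), "CtExperiment")))
    if (length(xs) == 1L)
        return(xs[[1L]])
    ref <- colnames(xs[[1L]])
    for (x in xs[-1L]) {
        if (!setequal(colnames(x), ref)) {
            d <- union(setdiff(ref, colnames(x)), setdiff(colnames(x), ref))
            stop("plates measure different sample sets; mismatched: ",
                 paste(sort(d), collapse = ", "), call. = FALSE)
        }
    }
    xs <- lapply(xs, function(x) x[, ref])
    out <- do.call(rbind, xs)
    new("CtExperiment", out)
}

#' Summarize a plate layout by well role
#'
#' @param x a [CtExperiment-class] or a layout `DataFrame`/`data.frame` with
#'   a `role` column.
#' @return data.frame of per-role well counts plus a `total` row; counts sum
#'   to the number of wells.
#' @examples
#' summarizeLayout(standardLayout())
#' @export
summarizeLayout <- function(x) {
    role <- if (is(x, "CtExperiment")) rowData(x)$role else x$role
    if (is.null(role) || !length(role))
        stop("layout is empty or lacks a 'role' column", call. = FALSE)
    counts <- table(factor(as.character(role), levels = .WELL_ROLES))
    data.frame(role = c(names(counts), "total"),
               wells = c(as.integer(counts), length(role)),
               stringsAsFactors = FALSE)
}

#' Write plate inputs back to disk
#'
#' Writers mirroring the three readers; round trips are lossless on values
#' and not-detected masks. Used by the simulator and in tests.
#'
#' @param x object to write (Ct matrix, layout, or sample sheet data.frame).
#' @param path destination file.
#' @param missingMarker string written for `NA` cells (default
#'   `"Undetermined"`).
#' @name plate-writers
NULL

#' @rdname plate-writers
#' @export
writeCtTable <- function(x, path, missingMarker = "Undetermined") {
    stopifnot(is.matrix(x))
    chr <- matrix(formatC(x, format = "g", digits = 15), nrow(x),
                  dimnames = dimnames(x))
    chr[is.na(x)] <- missingMarker
    df <- data.frame(well = rownames(x), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname plate-writers
#' @export
writeWellAnnotation <- function(x, path) {
    df <- as.data.frame(x)[, c("plate", "well", "assay", "role")]
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname plate-writers
#' @export
writeSampleSheet <- function(x, path) {
    utils::write.table(x[, c("sample", "group")], path, sep = ",",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
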