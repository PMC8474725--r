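#' @include de.R
NULL

#' Load an offline miRNA-target table
#'
#' Reads a TSV of miRNA-target interactions with header columns `mirna`,
#' `gene`, `source`, `evidence` and optionally `score`. `evidence` must be
#' `VALIDATED` or `PREDICTED` (case-insensitive). Duplicate (mirna, gene,
#' source) rows are collapsed. The file format is an offline snapshot of
#' target databases (miRTarBase, TarBase, DIANA-microT and the like), so the
#' mapping step is reproducible and needs no network access; users can
#' export any such database to this four/five-column TSV.
#'
#' @param path TSV file path.
#' @return data.frame (class `targetTable`) with columns `mirna`, `gene`,
#'   `source`, `evidence`, `score`; attribute `sourceCounts` logs rows per
#'   source database.
#' @export
loadTargetTable <- function(path) {
    df <- .readDelimChar(path, delim = "\t")
    names(df) <- tolower(names(df))
    need <- c("mirna", "gene", "source", "evidence")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("target table lacks column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    if (nrow(df) == 0L) {
        warning("target table is empty", call. = FALSE)
        out <- data.frame(mirna = character(), gene = character(),
                          source = character(), evidence = character(),
                          score = numeric(), stringsAsFactors = FALSE)
        class(out) <- c("targetTable", "data.frame")
        return(out)
    }
    ev <- toupper(trimws(df$evidence))
    bad <- !(ev %in% c("VALIDATED", "PREDICTED"))
    if (any(bad))
        stop("unknown evidence value '", df$evidence[which(bad)[1L]],
             "' at target table row ", which(bad)[1L], call. = FALSE)
    if (any(!nzchar(df$mirna)) || any(!nzchar(df$gene)))
        stop("empty mirna or gene field in target table", call. = FALSE)
    score <- if ("score" %in% names(df))
        suppressWarnings(as.numeric(df$score)) else NA_real_
    out <- data.frame(mirna = df$mirna, gene = df$gene, source = df$source,
                      evidence = ev, score = score, stringsAsFactors = FALSE)
    out <- out[!duplicated(out[, c("mirna", "gene", "source")]), ,
               drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sourceCounts") <- table(out$source)
    class(out) <- c("targetTable", "data.frame")
    out
}

#' Target genes of a miRNA list
#'
#' Union of genes targeted by any query miRNA, with per-gene provenance.
#' miRNA names are matched exactly after case-folding and whitespace
#' trimming; no -3p/-5p arm expansion is attempted (expansion would silently
#' change results). Genes supported by fewer than `minSources` distinct
#' source databases (counted across all supporting interactions passing the
#' evidence filter) are excluded.
#'
#' @param mirnas character vector of query miRNA ids (non-empty).
#' @param table a `targetTable` from [loadTargetTable()].
#' @param evidence `"both"` (default), `"validated"` or `"predicted"`.
#' @param minSources minimum distinct supporting source databases per gene
#'   (default 1).
#' @return data.frame with one row per gene: `gene`, `mirnas` (supporting
#'   miRNAs, `;`-joined), `sources` (`;`-joined), `nSources`. Zero rows plus
#'   a warning when no query miRNA appears in the table.
#' @export
targetsFor <- function(mirnas, table,
                       evidence = c("both", "validated", "predicted"),
                       minSources = 1) {
    evidence <- match.arg(evidence)
    stopifnot(length(mirnas) >= 1L, inherits(table, "data.frame"),
              minSources >= 1)
    tb <- as.data.frame(table)
    if (evidence != "both")
        tb <- tb[tb$evidence == toupper(evidence), , drop = FALSE]
    hit <- tb[.foldAssay(tb$mirna) %in% .foldAssay(mirnas), , drop = FALSE]
    if (nrow(hit) == 0L) {
        warning("no query miRNA has targets in the table",
                if (evidence != "both")
                    paste0(" with evidence ", toupper(evidence)) else "",
                call. = FALSE)
        return(data.frame(gene = character(), mirnas = character(),
                          sources = character(), nSources = integer(),
                          stringsAsFactors = FALSE))
    }
    bygene <- split(hit, hit$gene)
    out <- data.frame(
        gene = names(bygene),
        mirnas = vapply(bygene, function(d)
            paste(sort(unique(d$mirna)), collapse = ";"), character(1)),
        sources = vapply(bygene, function(d)
            paste(sort(unique(d$source)), collapse = ";"), character(1)),
        nSources = vapply(bygene, function(d)
            length(unique(d$source)), integer(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    out <- out[out$nSources >= minSources, , drop = FALSE]
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
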