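#' @include de.R
NULL

#' Hierarchical clustering of significant miRNAs
#'
#' Restricts the normalized matrix to the miRNAs called significant in a
#' differential-expression table, z-scores each row, and clusters rows and
#' columns by agglomerative hierarchical clustering (Euclidean distance,
#' complete linkage). Deterministic given its input. With fewer than two
#' significant miRNAs the heatmap is skipped: the function returns `NULL`
#' with a message rather than an error, because a run with one or zero hits
#' is a legitimate outcome.
#'
#' @param x a [NormalizedCtExperiment-class]
#' @param deTable table from [moderatedTTable()] /
#'   [differentialExpression()]; rows with `significant == TRUE` are used.
#' @return `NULL`, or a list with `matrix` (z-scored values, rows in
#'   dendrogram order), `rowOrder`, `colOrder`, `rowHclust`, `colHclust`.
#' @export
clusterSignificant <- function(x, deTable) {
    stopifnot(is(x, "NormalizedCtExperiment"),
              all(c("mirna", "significant") %in% colnames(deTable)))
    sig <- deTable$mirna[deTable$significant]
    sig <- intersect(sig, rownames(x))
    if (length(sig) < 2L || ncol(x) < 2L) {
        message("fewer than 2 significant miRNAs (or samples); ",
                "heatmap skipped")
        return(NULL)
    }
    m <- assay(x, "negDeltaCt")[sig, , drop = FALSE]
    z <- zScoreRows(m)
    rh <- stats::hclust(stats::dist(z), method = "complete")
    ch <- stats::hclust(stats::dist(t(z)), method = "complete")
    list(matrix = z[rh$order, ch$order, drop = FALSE],
         rowOrder = rownames(z)[rh$order],
         colOrder = colnames(z)[ch$order],
         rowHclust = rh, colHclust = ch)
}

#' Row-wise z-scoring
#'
#' Centers and scales each row to mean 0, sd 1 (complete-case per row);
#' constant rows scale to all zeros instead of dividing by zero.
#'
#' @param m numeric matrix
#' @return matrix of the same shape.
#' @export
zScoreRows <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- Inf    # constant row -> zeros
    (m - mu) / sd
}
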