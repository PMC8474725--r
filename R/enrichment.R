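#' @include targets.R
NULL

#' Load gene sets from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: set name,
#' description, then member genes, one set per line. Duplicate members
#' within a set are stored once; empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list (class `geneSetCollection`) of character gene
#'   vectors; per-set descriptions in `attr(, "description")`.
#' @export
loadGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop("GMT file '", path, "' is empty", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields",
             call. = FALSE)
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene-set name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "),
             call. = FALSE)
    desc <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- nm
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("dropping empty gene set(s): ",
                paste(nm[empty], collapse = ", "), call. = FALSE)
        sets <- sets[!empty]
        desc <- desc[!empty]
    }
    attr(sets, "description") <- setNames(desc, names(sets))
    class(sets) <- c("geneSetCollection", "list")
    sets
}

#' Upper-tail hypergeometric p-value
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N`, `K`, `n`): drawing
#' `n` genes from a universe of `N` of which `K` are in the set, the chance
#' of at least `k` hits. The tail is accumulated in log space
#' (log-binomial coefficients combined by log-sum-exp) for numerical
#' stability at large counts.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K gene-set size within the universe.
#' @param n query-list size within the universe.
#' @param N universe size; `K, n <= N`.
#' @return p-value in `(0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeometricPvalue(3, 5, 6, 20)
#' @export
hypergeometricPvalue <- function(k, K, n, N) {
    stopifnot(length(k) == 1L, k >= 0, K >= 0, n >= 0, N >= 1,
              K <= N, n <= N, k <= min(K, n))
    if (k == 0) return(1)
    j <- k:min(K, n)
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    mx <- max(lp)
    min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set for over-representation of the query genes by the
#' upper-tail hypergeometric test, after intersecting query and sets with
#' the universe. The default universe is the union of all genes in the
#' collection; pass an explicit `universe` (e.g. all genes in the target
#' table) to change the background. Sets outside `sizeRange` after
#' intersection are not tested (degenerate tests); p-values are
#' BH-adjusted across all tested sets.
#'
#' @param genes character query gene list.
#' @param collection a `geneSetCollection` from [loadGmt()], or a named
#'   list of character vectors.
#' @param universe optional explicit background gene vector.
#' @param sizeRange numeric length-2: sets tested only when their
#'   universe-intersected size is within this range (default `c(2, 2000)`).
#' @param reportAll also return sets with zero overlap (default `FALSE`).
#' @return data.frame sorted by p-value: `set`, `description`, `k`
#'   (overlap), `K` (set size), `n` (query size), `N` (universe size),
#'   `pValue`, `adjP`, `genes` (`;`-joined overlap).
#' @export
enrich <- function(genes, collection, universe = NULL,
                   sizeRange = c(2, 2000), reportAll = FALSE) {
    stopifnot(is.list(collection), length(collection) >= 1L,
              length(sizeRange) == 2L)
    if (is.null(universe))
        universe <- unique(unlist(collection, use.names = FALSE))
    universe <- unique(universe)
    q <- unique(intersect(genes, universe))
    if (!length(q))
        stop("no query gene is in the universe; check gene identifiers ",
             "or supply an explicit universe", call. = FALSE)
    N <- length(universe)
    n <- length(q)
    sets <- lapply(collection, intersect, universe)
    K <- lengths(sets)
    tested <- K >= sizeRange[1L] & K <= sizeRange[2L]
    if (!any(tested))
        return(data.frame(set = character(), description = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), pValue = numeric(),
                          adjP = numeric(), genes = character(),
                          stringsAsFactors = FALSE))
    ov <- lapply(sets[tested], intersect, q)
    k <- lengths(ov)
    p <- mapply(hypergeometricPvalue, k = k, K = K[tested],
                MoreArgs = list(n = n, N = N))
    desc <- attr(collection, "description")
    out <- data.frame(
        set = names(sets)[tested],
        description = if (is.null(desc)) "" else
            unname(desc[names(sets)[tested]]),
        k = unname(k), K = unname(K[tested]), n = n, N = N,
        pValue = unname(p), adjP = benjaminiHochberg(unname(p)),
        genes = vapply(ov, function(g) paste(sort(g), collapse = ";"),
                       character(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    if (!reportAll)
        out <- out[out$k > 0L, , drop = FALSE]
    out <- out[order(out$pValue, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}
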