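## Independent brute-force oracles used across the suite. These deliberately
## do not share code with the package implementation.

## Exact hypergeometric upper tail by direct enumeration of choose() products.
enumHyperTail <- function(k, K, n, N) {
    if (k == 0) return(1)
    hi <- min(K, n)
    if (k > hi) return(0)
    tot <- 0
    for (j in k:hi)
        tot <- tot + choose(K, j) * choose(N - K, n - j)
    tot / choose(N, n)
}

## Naive O(n^3) complete-linkage agglomeration; returns the cophenetic
## distance matrix (merge height of the first cluster joining each pair).
naiveCompleteLinkage <- function(m) {
    n <- nrow(m)
    d <- as.matrix(dist(m))
    clusters <- as.list(seq_len(n))
    coph <- matrix(0, n, n)
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestH <- Inf
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            h <- max(d[clusters[[a]], clusters[[b]]])
            if (h < bestH) { bestH <- h; best <- c(a, b) }
        }
        ia <- clusters[[best[1L]]]; ib <- clusters[[best[2L]]]
        coph[ia, ib] <- bestH; coph[ib, ia] <- bestH
        clusters[[best[1L]]] <- c(ia, ib)
        clusters[[best[2L]]] <- NULL
    }
    coph
}

## Exclusive NA-subset counts by brute force over every sample subset.
enumNaOverlap <- function(missMatrix) {
    samples <- colnames(missMatrix)
    out <- list()
    for (bits in seq_len(2^length(samples) - 1L)) {
        inset <- as.logical(bitwAnd(bits, 2^(seq_along(samples) - 1L)))
        cnt <- sum(apply(missMatrix, 1L, function(r)
            all(r[inset]) && !any(r[!inset])))
        if (cnt > 0L)
            out[[paste(samples[inset], collapse = "&")]] <- cnt
    }
    out
}

## Tiny hand-rolled fixture: a 3-well mini-plate experiment built in code.
miniExperiment <- function(ct, roles = c("MIRNA", "RTC", "PPC"),
                           assays = c("miR-x", "miRTC", "PPC"),
                           groups = NULL) {
    if (is.null(colnames(ct)))
        colnames(ct) <- paste0("S", seq_len(ncol(ct)))
    layout <- S4Vectors::DataFrame(
        plate = "p1", well = paste0("A", seq_along(assays)),
        assay = assays, role = roles,
        row.names = paste0("p1:A", seq_along(assays)))
    rownames(ct) <- paste0("A", seq_along(assays))
    samples <- if (is.null(groups)) NULL else
        data.frame(sample = colnames(ct), group = groups,
                   stringsAsFactors = FALSE)
    CtExperiment(ct, layout, samples)
}

## Write a small delimited file and return its path.
tmpFile <- function(lines, ext = ".csv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
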