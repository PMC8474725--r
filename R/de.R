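#' @include normalize.R
NULL

#' Per-miRNA two-group linear model
#'
#' Fits the two-group mean-difference model to every miRNA row of a
#' normalized experiment, complete-case per row. For miRNA \eqn{g} with
#' \eqn{n_1} usable test and \eqn{n_2} usable reference samples:
#' \deqn{\hat\beta_g = \bar{y}_{test} - \bar{y}_{ref}} (the log2 fold
#' change, since the input is \eqn{-\Delta Ct}),
#' \eqn{s_g^2} the pooled within-group variance on \eqn{d_g = n_1 + n_2 - 2}
#' degrees of freedom, and \eqn{v_g = 1/n_1 + 1/n_2} the unscaled variance
#' of \eqn{\hat\beta_g}. Rows with fewer than `minPerGroup` usable values in
#' either group are dropped and listed in the `dropped` attribute.
#'
#' @param x a [NormalizedCtExperiment-class] with group labels.
#' @param contrast character pair `c(test, reference)`; log fold changes are
#'   test minus reference.
#' @param minPerGroup minimum usable samples per group per miRNA
#'   (default 2).
#' @return data.frame (class `mirFit`) with columns `mirna`, `logFC`, `s2`,
#'   `df`, `v`, `nTest`, `nRef`; attributes `contrast` and `dropped`.
#' @export
fitGroupModel <- function(x, contrast, minPerGroup = 2) {
    stopifnot(is(x, "NormalizedCtExperiment"), length(contrast) == 2L)
    grp <- sampleGroups(x)
    if (length(unique(grp[!is.na(grp)])) < 2L)
        stop("differential analysis needs at least two sample groups",
             call. = FALSE)
    miss <- setdiff(contrast, grp)
    if (length(miss))
        stop("contrast group(s) absent from samples: ",
             paste(miss, collapse = ", "), call. = FALSE)
    y <- assay(x, "negDeltaCt")
    it <- which(grp == contrast[1L])
    ir <- which(grp == contrast[2L])
    n1 <- rowSums(!is.na(y[, it, drop = FALSE]))
    n2 <- rowSums(!is.na(y[, ir, drop = FALSE]))
    usable <- n1 >= minPerGroup & n2 >= minPerGroup
    dropped <- rownames(y)[!usable]
    if (!any(usable))
        stop("no miRNA has enough usable samples in both groups",
             call. = FALSE)
    yt <- y[usable, it, drop = FALSE]
    yr <- y[usable, ir, drop = FALSE]
    m1 <- rowMeans(yt, na.rm = TRUE)
    m2 <- rowMeans(yr, na.rm = TRUE)
    ss1 <- rowSums((yt - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((yr - m2)^2, na.rm = TRUE)
    n1 <- n1[usable]; n2 <- n2[usable]
    df <- n1 + n2 - 2
    out <- data.frame(
        mirna = rownames(yt), logFC = unname(m1 - m2),
        s2 = unname((ss1 + ss2) / df), df = unname(df),
        v = unname(1 / n1 + 1 / n2),
        nTest = unname(n1), nRef = unname(n2),
        stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "contrast") <- contrast
    attr(out, "dropped") <- dropped
    class(out) <- c("mirFit", "data.frame")
    out
}

## Inverse of the trigamma function by Newton iteration on 1/trigamma,
## which is nearly linear; converges in a handful of steps.
trigammaInverse <- function(x) {
    stopifnot(all(x > 0))
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (max(abs(dif / y)) < 1e-10) break
    }
    y
}

#' Empirical-Bayes moderation hyperparameters
#'
#' Estimates the prior degrees of freedom \eqn{d_0} and prior variance
#' \eqn{s_0^2} of the scaled inverse-chi-square prior on the per-miRNA
#' residual variances, by moment matching on \eqn{\log s_g^2}. Under the
#' model \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)}, the residuals
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)} have variance
#' \eqn{\psi'(d_g/2) + \psi'(d_0/2)}; the excess of the empirical variance
#' of \eqn{e_g} over its sampling part \eqn{\psi'(d_g/2)} is inverted
#' through the trigamma function to give \eqn{d_0}. When there is no excess
#' dispersion, \eqn{d_0 = \infty} and \eqn{s_0^2} is the mean observed
#' variance.
#'
#' @param fit a `mirFit` from [fitGroupModel()], or a numeric vector of
#'   variances (then `df` must be given).
#' @param df residual degrees of freedom (recycled) when `fit` is a plain
#'   vector.
#' @return list with elements `d0` (prior df, possibly `Inf`) and `s02`
#'   (prior variance).
#' @export
estimateModeration <- function(fit, df = NULL) {
    if (inherits(fit, "mirFit")) {
        s2 <- fit$s2; dg <- fit$df
    } else {
        s2 <- as.numeric(fit)
        if (is.null(df)) stop("df required when fit is a plain vector")
        dg <- rep_len(df, length(s2))
    }
    ok <- is.finite(s2) & s2 > 0 & dg > 0
    if (all(s2[dg > 0] == 0))
        stop("all residual variances are exactly zero; the data look ",
             "degenerate (identical replicates?)", call. = FALSE)
    if (sum(ok) < 2L)
        stop("need at least two positive variances with df > 0 to ",
             "estimate moderation", call. = FALSE)
    s2 <- s2[ok]; dg <- dg[ok]
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    excess <- stats::var(e) - mean(trigamma(dg / 2))
    if (is.finite(excess) && excess > 0) {
        d0 <- 2 * trigammaInverse(excess)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- mean(s2)
    }
    list(d0 = d0, s02 = s02)
}

#' Moderated t-statistics and the differential-expression table
#'
#' Shrinks each miRNA's residual variance toward the prior,
#' \deqn{\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' forms the moderated t-statistic
#' \eqn{\tilde{t}_g = \hat\beta_g / \sqrt{\tilde{s}_g^2 v_g}} on
#' \eqn{d_0 + d_g} degrees of freedom (standard normal when \eqn{d_0 =
#' \infty}), and attaches two-sided p-values with multiplicity adjustment.
#' At \eqn{d_0 = 0} this is exactly the classic pooled two-sample t-test;
#' at \eqn{d_0 = \infty} every variance equals \eqn{s_0^2}.
#'
#' @param fit a `mirFit` from [fitGroupModel()].
#' @param params moderation parameters from [estimateModeration()] (list
#'   with `d0`, `s02`).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame sorted by p-value: `mirna`, `logFC`, `t`, `pValue`,
#'   `adjP`, `significant`, `nTest`, `nRef`, `df`.
#' @export
moderatedTTable <- function(fit, params, alpha = 0.05,
                            adjust = c("BH", "bonferroni")) {
    adjust <- match.arg(adjust)
    stopifnot(inherits(fit, "mirFit"), is.list(params),
              params$d0 >= 0, params$s02 > 0, alpha > 0, alpha <= 1)
    d0 <- params$d0; s02 <- params$s02
    if (is.infinite(d0)) {
        stilde2 <- rep(s02, nrow(fit))
        dfTotal <- rep(Inf, nrow(fit))
    } else {
        stilde2 <- (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
        dfTotal <- d0 + fit$df
    }
    tmod <- fit$logFC / sqrt(stilde2 * fit$v)
    p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
    adjP <- if (adjust == "BH") benjaminiHochberg(p)
            else pmin(1, p * length(p))
    out <- data.frame(
        mirna = fit$mirna, logFC = fit$logFC, t = tmod, pValue = p,
        adjP = adjP, significant = adjP < alpha,
        nTest = fit$nTest, nRef = fit$nRef, df = dfTotal,
        stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$pValue, -abs(out$t)), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "contrast") <- attr(fit, "contrast")
    attr(out, "dropped") <- attr(fit, "dropped")
    attr(out, "alpha") <- alpha
    attr(out, "moderation") <- params
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{adj_{(i)} = \min_{j \ge i} \ m \, p_{(j)} / j}, capped at 1 and
#' returned in the input order. Controls the false discovery rate for
#' independent or positively dependent tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order; always `>= p`.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, adj)[order(o)]
}

#' Differential expression in one call
#'
#' [fitGroupModel()] then [estimateModeration()] then [moderatedTTable()].
#'
#' @inheritParams fitGroupModel
#' @inheritParams moderatedTTable
#' @return the moderated differential-expression table.
#' @examples
#' sim <- simulatePlates(simulationScenario(seed = 11))
#' nse <- normalizeCt(applyQC(sim$experiment)$experiment)
#' de <- differentialExpression(nse, contrast = c("tumor", "normal"))
#' head(de)
#' @export
differentialExpression <- function(x, contrast, alpha = 0.05,
                                   adjust = c("BH", "bonferroni"),
                                   minPerGroup = 2) {
    fit <- fitGroupModel(x, contrast, minPerGroup = minPerGroup)
    params <- estimateModeration(fit)
    moderatedTTable(fit, params, alpha = alpha, adjust = adjust)
}
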