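## build a NormalizedCtExperiment directly from a value matrix
nseFrom <- function(y, groups) {
    if (is.null(rownames(y)))
        rownames(y) <- sprintf("miR-%03d", seq_len(nrow(y)))
    if (is.null(colnames(y)))
        colnames(y) <- sprintf("S%d", seq_len(ncol(y)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(negDeltaCt = y),
        colData = S4Vectors::DataFrame(group = groups,
                                       referenceCt = rep(20, ncol(y)),
                                       row.names = colnames(y)))
    new("NormalizedCtExperiment", se)
}

test_that("the two-group fit returns hand-computed moments", {
    y <- rbind(c(1, 1, 0, 0),
               c(2, 0, 1, -1))
    fit <- fitGroupModel(nseFrom(y, c("T", "T", "R", "R")),
                         contrast = c("T", "R"))
    expect_equal(fit$logFC, c(1, 1))
    expect_equal(fit$s2, c(0, 2))        # pooled: (2 + 2) / 2 for row 2
    expect_equal(fit$df, c(2, 2))
    expect_equal(fit$v, c(1, 1))

    ## a miRNA with one usable test sample is dropped and listed
    y2 <- rbind(c(1, NA, NA, 0, 1, 1), c(1, 2, 0, 1, 0, 2))
    rownames(y2) <- c("miR-one", "miR-two")
    fit2 <- fitGroupModel(nseFrom(y2, rep(c("T", "R"), each = 3)),
                          contrast = c("T", "R"))
    expect_identical(fit2$mirna, "miR-two")
    expect_identical(attr(fit2, "dropped"), "miR-one")

    expect_error(fitGroupModel(nseFrom(y, rep("T", 4)),
                               contrast = c("T", "R")),
                 "two sample groups")
})

test_that("moderation hyperparameters are recovered from scaled-F draws", {
    set.seed(123)
    s2 <- 1 * rf(2000, df1 = 4, df2 = 4)   # d0 = 4, s02 = 1
    est <- estimateModeration(s2, df = 4)
    expect_lt(abs(est$d0 - 4) / 4, 0.25)
    expect_lt(abs(est$s02 - 1) / 1, 0.10)

    ## no excess dispersion: prior df is infinite, prior var the common one
    expect_identical(estimateModeration(rep(1.7, 50), df = 4)$d0, Inf)
    expect_equal(estimateModeration(rep(1.7, 50), df = 4)$s02, 1.7)
    expect_identical(estimateModeration(c(1, 1), df = 4)$d0, Inf)
    expect_error(estimateModeration(c(0, 0), df = 4), "zero")
})

test_that("moderation matches limma's empirical-Bayes estimator", {
    set.seed(9)
    y <- matrix(rnorm(200 * 8, sd = rep(sqrt(1 / rgamma(200, 3, 3)), 8)),
                200, 8)
    grp <- rep(c("B", "A"), each = 4)
    fit <- fitGroupModel(nseFrom(y, grp), contrast = c("B", "A"))
    est <- estimateModeration(fit)
    lf <- limma::fitFDist(fit$s2, df1 = fit$df)
    expect_equal(est$d0, lf$df2, tolerance = 1e-10)
    expect_equal(est$s02, lf$scale, tolerance = 1e-10)

    ## full moderated table against limma lmFit + eBayes
    design <- stats::model.matrix(~ 0 + factor(grp, levels = c("A", "B")))
    colnames(design) <- c("A", "B")
    lfit <- limma::contrasts.fit(limma::lmFit(y, design), c(-1, 1))
    eb <- limma::eBayes(lfit)
    tab <- moderatedTTable(fit, est)
    ord <- match(sprintf("miR-%03d", seq_len(nrow(y))), tab$mirna)
    expect_equal(tab$logFC[ord], unname(eb$coefficients[, 1]),
                 tolerance = 1e-10)
    expect_equal(tab$t[ord], unname(eb$t[, 1]), tolerance = 1e-8)
    expect_equal(tab$pValue[ord], unname(eb$p.value[, 1]),
                 tolerance = 1e-8)
})

test_that("moderated t collapses to the classic pooled t at d0 = 0", {
    set.seed(42)
    y <- matrix(rnorm(100 * 10), 100, 10)
    grp <- rep(c("T", "R"), each = 5)
    fit <- fitGroupModel(nseFrom(y, grp), contrast = c("T", "R"))
    tab <- moderatedTTable(fit, list(d0 = 0, s02 = 1))
    ord <- match(sprintf("miR-%03d", 1:100), tab$mirna)
    for (g in 1:100) {
        tt <- t.test(y[g, grp == "T"], y[g, grp == "R"],
                     var.equal = TRUE)
        expect_equal(tab$t[ord[g]], unname(tt$statistic),
                     tolerance = 1e-12)
        expect_equal(tab$pValue[ord[g]], tt$p.value, tolerance = 1e-12)
    }
})

test_that("moderated t limits and the frozen textbook example hold", {
    fit1 <- structure(
        data.frame(mirna = "m1", logFC = 1, s2 = 1, df = 2, v = 1,
                   nTest = 2, nRef = 2),
        class = c("mirFit", "data.frame"), contrast = c("T", "R"),
        dropped = character())
    ## beta=1, s2=1, d=2, d0=2, s02=1, v=1: stilde2 = 1, t = 1, df = 4
    tab <- moderatedTTable(fit1, list(d0 = 2, s02 = 1))
    expect_equal(tab$t, 1)
    expect_equal(tab$df, 4)
    expect_equal(tab$pValue, 0.3739, tolerance = 1e-4)
    expect_equal(tab$pValue, 2 * pt(-1, df = 4), tolerance = 1e-12)

    ## d0 = Inf: every variance becomes s02, reference normal
    set.seed(1)
    y <- matrix(rnorm(20 * 6), 20, 6)
    fit <- fitGroupModel(nseFrom(y, rep(c("T", "R"), each = 3)),
                         contrast = c("T", "R"))
    tabInf <- moderatedTTable(fit, list(d0 = Inf, s02 = 0.5))
    expect_equal(tabInf$t, tabInf$logFC / sqrt(0.5 * fit$v[
        match(tabInf$mirna, fit$mirna)]), tolerance = 1e-12)
    expect_equal(tabInf$pValue, 2 * pnorm(-abs(tabInf$t)),
                 tolerance = 1e-12)
})

test_that("swapping the contrast negates effects and keeps p-values", {
    sim <- simulatePlates(simulationScenario(seed = 10))
    nse <- normalizeCt(applyQC(sim$experiment)$experiment)
    a <- differentialExpression(nse, contrast = c("tumor", "normal"))
    b <- differentialExpression(nse, contrast = c("normal", "tumor"))
    ord <- match(a$mirna, b$mirna)
    expect_equal(a$logFC, -b$logFC[ord], tolerance = 1e-12)
    expect_equal(a$t, -b$t[ord], tolerance = 1e-12)
    expect_equal(a$pValue, b$pValue[ord], tolerance = 1e-12)
    expect_equal(a$adjP, b$adjP[ord], tolerance = 1e-12)
})

test_that("Benjamini-Hochberg matches hand computation and p.adjust", {
    expect_equal(benjaminiHochberg(0.03), 0.03)
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.04)),
                 c(0.03, 0.03, 0.04))
    expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")

    set.seed(31)
    for (i in 1:20) {
        p <- runif(sample(1:10, 1))
        adj <- benjaminiHochberg(p)
        expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
        expect_true(all(adj >= p - 1e-15))
        ## order-invariance up to the same permutation
        perm <- sample(length(p))
        expect_equal(benjaminiHochberg(p[perm]), adj[perm],
                     tolerance = 1e-12)
    }
})
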