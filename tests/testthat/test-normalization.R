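test_that("replicate wells collapse by the mean of observed Cts", {
    x <- miniExperiment(rbind(c(21, 22), c(18.0, 20.0), c(18.4, NA)),
                        roles = c("MIRNA", "CE_SPIKE", "CE_SPIKE"),
                        assays = c("miR-x", "cel-miR-39", "cel-miR-39"))
    coll <- collapseReplicates(x)
    expect_identical(nrow(coll), 2L)
    cm <- SummarizedExperiment::assay(coll, "ct")
    expect_equal(cm["cel-miR-39", ], c(S1 = 18.2, S2 = 20.0))
    expect_equal(cm["miR-x", ], c(S1 = 21, S2 = 22))   # singleton: identity
    ## missing only when every replicate is missing
    y <- miniExperiment(rbind(c(21, 22), c(NA, NA), c(NA, 19)),
                        roles = c("MIRNA", "CE_SPIKE", "CE_SPIKE"),
                        assays = c("miR-x", "cel-miR-39", "cel-miR-39"))
    cy <- SummarizedExperiment::assay(collapseReplicates(y), "ct")
    expect_true(is.na(cy["cel-miR-39", "S1"]))
    expect_equal(cy["cel-miR-39", "S2"], 19)
})

test_that("reference Ct averages the available control assays", {
    ctl <- c("SNORD61", "SNORD68", "SNORD72", "SNORD95", "SNORD96A",
             "RNU6B")
    x <- miniExperiment(
        matrix(c(rep(20, 6), c(20, 20, 20, 20, 20, 26)), ncol = 2,
               dimnames = list(NULL, c("S1", "S2"))),
        roles = rep("SNORNA_SNRNA", 6), assays = ctl)
    ref <- referenceCt(collapseReplicates(x), mode = "endogenous")
    expect_equal(as.numeric(ref), c(20, 21))
    used <- attr(ref, "controlsUsed")
    expect_identical(sort(used$S1), sort(ctl))

    ## exogenous mode picks up the spike-in
    y <- miniExperiment(rbind(c(25, 26), c(18.0, 18.0), c(18.4, 18.4)),
                        roles = c("MIRNA", "CE_SPIKE", "CE_SPIKE"),
                        assays = c("miR-x", "cel-miR-39", "cel-miR-39"))
    refy <- referenceCt(collapseReplicates(y), mode = "exogenous")
    expect_equal(as.numeric(refy), c(18.2, 18.2))

    ## a sample with every control missing is an error naming it
    z <- miniExperiment(rbind(c(25, 26), c(NA, 18)),
                        roles = c("MIRNA", "CE_SPIKE"),
                        assays = c("miR-x", "cel-miR-39"))
    expect_error(referenceCt(collapseReplicates(z), mode = "exogenous"),
                 "S1")
})

test_that("delta-Ct normalization has the -deltaCt sign convention", {
    x <- miniExperiment(rbind(c(20, 18, NA), c(20, 20, 20)),
                        roles = c("MIRNA", "SNORNA_SNRNA"),
                        assays = c("miR-x", "RNU6B"))
    colnames(x) <- c("S1", "S2", "S3")
    nse <- normalizeCt(x, mode = "endogenous")
    expect_s4_class(nse, "NormalizedCtExperiment")
    v <- SummarizedExperiment::assay(nse, "negDeltaCt")
    expect_equal(v["miR-x", "S1"], 0)    # Ct equal to reference
    expect_equal(v["miR-x", "S2"], 2)    # 2 cycles below ref: 4-fold up
    expect_true(is.na(v["miR-x", "S3"])) # mask propagates
    expect_identical(rownames(nse), "miR-x")  # control rows removed
    ## linear companion scale
    expect_equal(unname(relativeExpression(nse)[1, 1:2]), c(1, 4))
    expect_equal(relativeExpression(nse)["miR-x", "S2"], 4)
    d <- miniExperiment(rbind(c(23), c(20)),
                        roles = c("MIRNA", "SNORNA_SNRNA"),
                        assays = c("miR-x", "RNU6B"))
    expect_equal(unname(relativeExpression(
        normalizeCt(d, "endogenous"))[1, 1]), 0.125)
})

test_that("per-sample global Ct shifts leave normalized values unchanged", {
    sim <- simulatePlates(simulationScenario(seed = 6, naRate = 0,
                                             sampleShiftSd = 0))
    x <- sim$experiment
    nse0 <- normalizeCt(x)
    ## add an arbitrary constant per sample to EVERY well, controls included
    shifts <- seq(-3, 3, length.out = ncol(x))
    ct <- sweep(ctValues(x), 2L, shifts, "+")
    SummarizedExperiment::assay(x, "ct") <- ct
    nseS <- normalizeCt(x)
    expect_equal(SummarizedExperiment::assay(nseS, "negDeltaCt"),
                 SummarizedExperiment::assay(nse0, "negDeltaCt"),
                 tolerance = 1e-12)
    ## same for the exogenous mode
    expect_equal(
        SummarizedExperiment::assay(normalizeCt(x, "exogenous"),
                                    "negDeltaCt"),
        SummarizedExperiment::assay(normalizeCt(sim$experiment,
                                                "exogenous"),
                                    "negDeltaCt"),
        tolerance = 1e-12)
    ## per-sample medians of -deltaCt are shift-invariant as a consequence
    expect_equal(apply(SummarizedExperiment::assay(nseS, "negDeltaCt"),
                       2L, median, na.rm = TRUE),
                 apply(SummarizedExperiment::assay(nse0, "negDeltaCt"),
                       2L, median, na.rm = TRUE), tolerance = 1e-12)
})

test_that("endogenous and exogenous modes agree when control means agree", {
    x <- miniExperiment(
        rbind(c(25, 27), c(19, 20), c(21, 22), c(20, 21)),
        roles = c("MIRNA", "SNORNA_SNRNA", "SNORNA_SNRNA", "CE_SPIKE"),
        assays = c("miR-x", "SNORD61", "RNU6B", "cel-miR-39"))
    ## endogenous mean (19+21)/2 = 20 = spike-in mean in S1; 21 in S2
    a <- SummarizedExperiment::assay(normalizeCt(x, "endogenous"),
                                     "negDeltaCt")
    b <- SummarizedExperiment::assay(normalizeCt(x, "exogenous"),
                                     "negDeltaCt")
    expect_equal(a, b, tolerance = 1e-12)
})
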