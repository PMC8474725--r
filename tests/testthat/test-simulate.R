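test_that("the generated standard layout matches the plate format", {
    lay <- standardLayout()
    s <- summarizeLayout(lay)
    counts <- setNames(s$wells, s$role)
    expect_identical(counts[["total"]], 384L)
    expect_identical(counts[["MIRNA"]], 372L)
    expect_identical(counts[["CE_SPIKE"]], 2L)
    expect_identical(counts[["SNORNA_SNRNA"]], 6L)
    expect_identical(counts[["RTC"]], 2L)
    expect_identical(counts[["PPC"]], 2L)
    ## the named endogenous panel is present
    expect_true(all(c("SNORD61", "SNORD68", "SNORD72", "SNORD95",
                      "SNORD96A", "RNU6B") %in% lay$assay))
    ## deterministic and identical to the bundled fixture
    expect_identical(standardLayout(), lay)
    bundled <- readWellAnnotation(
        system.file("extdata", "standard_layout.csv", package = "miRct"))
    expect_identical(as.character(bundled$assay), as.character(lay$assay))
})

test_that("the simulator is seed-deterministic and leaves the RNG alone", {
    a <- simulatePlates(simulationScenario(seed = 99))
    b <- simulatePlates(simulationScenario(seed = 99))
    expect_identical(ctValues(a$experiment), ctValues(b$experiment))
    expect_identical(a$truth$effects, b$truth$effects)
    c2 <- simulatePlates(simulationScenario(seed = 100))
    expect_false(identical(ctValues(a$experiment),
                           ctValues(c2$experiment)))
    ## caller's RNG stream is not consumed
    set.seed(5); before <- rnorm(1)
    set.seed(5); invisible(simulatePlates(simulationScenario(seed = 1)))
    expect_identical(rnorm(1), before)
})

test_that("a noiseless scenario with no effects gives identical groups", {
    sim <- simulatePlates(simulationScenario(
        nPerGroup = 3, nDe = 0, effectSize = 0, noiseSd = 0, naRate = 0,
        sampleShiftSd = 0, seed = 17))
    ct <- ctValues(sim$experiment)
    expect_equal(ct[, 1], ct[, 4], ignore_attr = TRUE)
    expect_identical(length(unique(as.vector(stats::cor(ct)))), 1L)
})

test_that("forced RT failures are excluded by QC with the RT reason", {
    sim <- simulatePlates(simulationScenario(
        seed = 23, rtFailSamples = c("tumor_3")))
    qc <- applyQC(sim$experiment)
    expect_identical(qc$report$sample[qc$report$excluded], "tumor_3")
    expect_identical(qc$report$reason[qc$report$excluded],
                     "RT efficiency")
})

test_that("planted effects appear in the normalized matrix as planted", {
    sc <- simulationScenario(seed = 42)   # effect 2 cycles, n = 6, sd 0.5
    sim <- simulatePlates(sc)
    nse <- normalizeCt(applyQC(sim$experiment)$experiment)
    y <- SummarizedExperiment::assay(nse, "negDeltaCt")
    grp <- sampleGroups(nse)
    diff <- rowMeans(y[, grp == "tumor"], na.rm = TRUE) -
        rowMeans(y[, grp == "normal"], na.rm = TRUE)
    eff <- sim$truth$effects
    ## per-miRNA SE ~ sd * sqrt(2/6) ~ 0.29; allow ~4 SEs
    expect_true(all(abs(diff[names(eff)] - eff) < 1.2))
    expect_lt(abs(mean(diff[names(eff)] - eff)), 0.2)
    ## non-planted miRNAs center on zero
    expect_lt(abs(mean(diff[setdiff(names(diff), names(eff))])), 0.1)
})

test_that("planted-effect recovery is unchanged as the shift sd varies", {
    recovered <- vapply(c(0, 3), function(ssd) {
        sim <- simulatePlates(simulationScenario(seed = 7,
                                                 sampleShiftSd = ssd))
        nse <- normalizeCt(applyQC(sim$experiment)$experiment)
        de <- differentialExpression(nse, c("tumor", "normal"))
        mean(sim$truth$deMirnas %in% de$mirna[de$significant])
    }, numeric(1))
    expect_true(all(recovered >= 0.8))
    expect_lt(abs(recovered[1] - recovered[2]), 0.15)
})

test_that("simulated target tables and gene sets satisfy their contracts", {
    tt <- simulateTargetTable(sprintf("miR-%02d", 1:10), nGenes = 60,
                              targetsPerMirna = 4, seed = 3)
    expect_s3_class(tt, "targetTable")
    expect_false(any(duplicated(tt[, c("mirna", "gene", "source")])))
    expect_true(all(tt$evidence[tt$source == "diana_microt"] ==
                        "PREDICTED"))
    expect_true(all(tt$evidence[tt$source != "diana_microt"] ==
                        "VALIDATED"))
    expect_identical(tt, simulateTargetTable(sprintf("miR-%02d", 1:10),
                                             nGenes = 60,
                                             targetsPerMirna = 4,
                                             seed = 3))

    gs <- simulateGeneSets(sprintf("G%03d", 1:100), nSets = 8,
                           sizeRange = c(5, 10), seed = 4)
    expect_identical(length(gs), 8L)
    expect_true(all(lengths(gs) >= 5 & lengths(gs) <= 10))
    f <- tempfile(fileext = ".gmt")
    writeGmt(gs, f)
    back <- loadGmt(f)
    expect_identical(unclass(back)[seq_along(back)],
                     unclass(gs)[seq_along(gs)])
})

test_that("impossible dropout scenarios are rejected", {
    expect_error(simulatePlates(simulationScenario(naRate = 1)),
                 "quality control")
    expect_error(simulationScenario(naRate = -0.1))
    expect_error(simulatePlates(simulationScenario(
        rtFailSamples = "nope")), "nope")
})
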