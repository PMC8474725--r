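#' @include enrichment.R
NULL

## run code under a fixed seed without clobbering the caller's RNG stream
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' The standard 384-well plate layout
#'
#' Builds the standard single-plate miScript-style layout: 384 wells (rows
#' A-P, columns 1-24), of which 372 hold miRNA assays and 12 hold controls
#' — 2 replicate cel-miR-39 spike-in wells, the 6 endogenous-control wells
#' (SNORD61, SNORD68, SNORD72, SNORD95, SNORD96A, RNU6B), 2 replicate miRTC
#' reverse-transcription controls and 2 PPC positive PCR controls. miRNA
#' assay names are synthetic placeholders (`syn-miR-001` ...); control
#' names are the vendor names. Deterministic: repeated calls are identical.
#'
#' @return [S4Vectors::DataFrame] layout with columns `plate`, `well`,
#'   `assay`, `role`, as from [readWellAnnotation()].
#' @examples
#' summarizeLayout(standardLayout())
#' @export
standardLayout <- function() {
    wells <- paste0(rep(LETTERS[1:16], each = 24L), rep(1:24, times = 16L))
    assay <- c(sprintf("syn-miR-%03d", 1:372),
               rep("cel-miR-39", 2L),
               .ENDOGENOUS_ASSAYS,
               rep("miRTC", 2L), rep("PPC", 2L))
    DataFrame(plate = "plate1", well = wells, assay = assay,
              role = .inferRole(assay),
              row.names = paste("plate1", wells, sep = ":"))
}

#' Describe a simulation scenario
#'
#' Collects and validates the knobs of the plate simulator. The defaults
#' describe the reference study conditions used throughout the package's
#' tests: 6 samples per group, 30 planted differentially expressed miRNAs
#' at 2 cycles effect size, 0.5 cycles well noise, 2% uniform dropout, and
#' per-sample global Ct offsets of sd 1 cycle emulating input-quantity
#' variation.
#'
#' @param nPerGroup samples per group.
#' @param groups two group labels; the second is the test group carrying
#'   the planted effects.
#' @param nDe number of planted differentially expressed miRNAs (half up,
#'   half down); at most 372.
#' @param effectSize planted absolute group difference, in cycles (= log2
#'   fold-change units).
#' @param noiseSd per-well measurement noise sd, cycles.
#' @param naRate uniform not-detected rate over miRNA wells, in `[0, 1)`.
#' @param sampleShiftSd sd of the per-sample global Ct offset applied to
#'   every well including controls, cycles.
#' @param rtFailSamples sample ids whose RTC wells are inflated so they
#'   fail the RT-efficiency check.
#' @param structuredDropout if `TRUE`, dropout probability grows with
#'   baseline Ct (abundance-dependent, as in real data) instead of uniform.
#' @param seed integer RNG seed.
#' @return validated scenario (list, class `simScenario`).
#' @export
simulationScenario <- function(nPerGroup = 6, groups = c("normal", "tumor"),
                               nDe = 30, effectSize = 2, noiseSd = 0.5,
                               naRate = 0.02, sampleShiftSd = 1,
                               rtFailSamples = character(),
                               structuredDropout = FALSE, seed = 1) {
    stopifnot(nPerGroup >= 1, length(groups) == 2L,
              !anyDuplicated(groups), nDe >= 0, nDe <= 372,
              effectSize >= 0, noiseSd >= 0, sampleShiftSd >= 0,
              naRate >= 0, naRate <= 1)
    sc <- list(nPerGroup = as.integer(nPerGroup), groups = groups,
               nDe = as.integer(nDe), effectSize = effectSize,
               noiseSd = noiseSd, naRate = naRate,
               sampleShiftSd = sampleShiftSd,
               rtFailSamples = rtFailSamples,
               structuredDropout = isTRUE(structuredDropout),
               seed = as.integer(seed))
    class(sc) <- "simScenario"
    sc
}

#' Simulate a plate experiment with known ground truth
#'
#' Generates a standard-layout [CtExperiment-class] under a
#' [simulationScenario()]: per-miRNA baseline Ct drawn uniformly on
#' 20-32 cycles, planted group effects on `nDe` miRNAs (Ct lowered in the
#' test group for up-regulated miRNAs and raised for down-regulated ones),
#' per-sample global offsets hitting every well including controls,
#' Gaussian well noise, uniform (or abundance-dependent) dropout over
#' miRNA wells, and optional forced RT failures. Same seed, same output,
#' bit for bit.
#'
#' @param scenario a `simScenario` from [simulationScenario()].
#' @return list with `experiment` (a [CtExperiment-class]), `samples` (the
#'   sample sheet data.frame) and `truth`: planted miRNA ids with signed
#'   log2 effects, per-sample shifts, injected NA positions, and the
#'   intended QC failures.
#' @examples
#' sim <- simulatePlates(simulationScenario(nPerGroup = 3, seed = 42))
#' sim$experiment
#' head(sim$truth$effects)
#' @export
simulatePlates <- function(scenario = simulationScenario()) {
    stopifnot(inherits(scenario, "simScenario"))
    if (scenario$naRate >= 1)
        stop("naRate = 1 leaves no detected miRNA wells; no sample could ",
             "ever pass quality control", call. = FALSE)
    layout <- standardLayout()
    withSeed(scenario$seed, {
        groups <- rep(scenario$groups, each = scenario$nPerGroup)
        samples <- data.frame(
            sample = sprintf("%s_%d", groups,
                             rep(seq_len(scenario$nPerGroup), times = 2L)),
            group = groups, stringsAsFactors = FALSE)
        bad <- setdiff(scenario$rtFailSamples, samples$sample)
        if (length(bad))
            stop("rtFailSamples not among simulated samples: ",
                 paste(bad, collapse = ", "), call. = FALSE)
        ns <- nrow(samples)
        mirna <- layout$assay[layout$role == "MIRNA"]

        baseline <- numeric(nrow(layout))
        names(baseline) <- layout$assay
        baseline[layout$role == "MIRNA"] <- stats::runif(372, 20, 32)
        baseline[layout$role == "CE_SPIKE"] <- 18
        baseline[layout$role == "SNORNA_SNRNA"] <- stats::runif(6, 19, 21)
        baseline[layout$role == "RTC"] <- 21
        baseline[layout$role == "PPC"] <- 19

        de <- sort(sample(mirna, scenario$nDe))
        effects <- setNames(rep(0, length(de)), de)
        if (length(de))
            effects[] <- scenario$effectSize *
                rep_len(c(1, -1), length(de))
        shifts <- setNames(stats::rnorm(ns, 0, scenario$sampleShiftSd),
                           samples$sample)

        ct <- matrix(baseline, nrow(layout), ns,
                     dimnames = list(rownames(layout), samples$sample))
        ct <- sweep(ct, 2L, shifts, "+")
        test <- samples$group == scenario$groups[2L]
        ide <- match(de, layout$assay)
        ct[ide, test] <- ct[ide, test] - effects   # lower Ct = more abundant
        ct <- ct + stats::rnorm(length(ct), 0, scenario$noiseSd)

        imir <- which(layout$role == "MIRNA")
        if (scenario$naRate > 0) {
            pdrop <- if (scenario$structuredDropout) {
                ## scale so the mean rate matches naRate, biased to high Ct
                w <- (baseline[imir] - 20) / 12
                pmin(0.95, scenario$naRate * length(w) * w / sum(w))
            } else rep(scenario$naRate, length(imir))
            drop <- matrix(stats::runif(length(imir) * ns) <
                               pdrop, length(imir), ns)
            ct[imir, ][drop] <- NA_real_
            naPositions <- data.frame(
                well = rownames(ct)[imir][row(drop)[drop]],
                sample = samples$sample[col(drop)[drop]],
                stringsAsFactors = FALSE)
        } else {
            naPositions <- data.frame(well = character(),
                                      sample = character(),
                                      stringsAsFactors = FALSE)
        }
        if (length(scenario$rtFailSamples)) {
            irtc <- layout$role == "RTC"
            ct[irtc, scenario$rtFailSamples] <-
                ct[irtc, scenario$rtFailSamples] + 8
        }

        exper <- CtExperiment(
            structure(ct, dimnames = list(layout$well, samples$sample)),
            layout, samples)
        list(experiment = exper,
             samples = samples,
             truth = list(deMirnas = de, effects = effects,
                          shifts = shifts, naPositions = naPositions,
                          rtFailSamples = scenario$rtFailSamples,
                          testGroup = scenario$groups[2L],
                          scenario = scenario))
    })
}

#' Simulate an offline miRNA-target table
#'
#' Draws a random many-to-many miRNA-target map over a synthetic gene
#' universe, with interactions attributed to emulated source databases
#' (mirtarbase and tarbase as VALIDATED, diana_microt as PREDICTED); a
#' fraction of interactions is supported by two sources.
#'
#' @param mirnas miRNA ids to cover (e.g. `standardLayout()` assay names).
#' @param nGenes size of the synthetic gene universe.
#' @param targetsPerMirna targets drawn per miRNA.
#' @param seed RNG seed.
#' @return a `targetTable` data.frame as from [loadTargetTable()].
#' @export
simulateTargetTable <- function(mirnas, nGenes = 300, targetsPerMirna = 8,
                                seed = 1) {
    stopifnot(length(mirnas) >= 1L, nGenes >= targetsPerMirna)
    genes <- sprintf("GENE%04d", seq_len(nGenes))
    src <- c(mirtarbase = "VALIDATED", tarbase = "VALIDATED",
             diana_microt = "PREDICTED")
    withSeed(seed, {
        rows <- lapply(mirnas, function(m) {
            g <- sample(genes, targetsPerMirna)
            s1 <- sample(names(src), targetsPerMirna, replace = TRUE)
            d <- data.frame(mirna = m, gene = g, source = s1,
                            stringsAsFactors = FALSE)
            dup <- stats::runif(targetsPerMirna) < 0.3
            if (any(dup)) {
                s2 <- vapply(s1[dup], function(s)
                    sample(setdiff(names(src), s), 1L), character(1))
                d <- rbind(d, data.frame(mirna = m, gene = g[dup],
                                         source = s2,
                                         stringsAsFactors = FALSE))
            }
            d
        })
        out <- do.call(rbind, rows)
        out$evidence <- unname(src[out$source])
        out$score <- NA_real_
        out <- out[!duplicated(out[, c("mirna", "gene", "source")]), ,
                   drop = FALSE]
        rownames(out) <- NULL
        attr(out, "sourceCounts") <- table(out$source)
        class(out) <- c("targetTable", "data.frame")
        out
    })
}

#' Simulate a gene-set collection
#'
#' Random gene sets over a gene universe, sized uniformly within
#' `sizeRange`; written to GMT with [writeGmt()] when needed on disk.
#'
#' @param genes gene universe to draw from.
#' @param nSets number of sets.
#' @param sizeRange integer length-2 range of set sizes.
#' @param seed RNG seed.
#' @return a `geneSetCollection` (named list of gene vectors).
#' @export
simulateGeneSets <- function(genes, nSets = 20, sizeRange = c(10, 40),
                             seed = 1) {
    stopifnot(length(genes) >= max(sizeRange), nSets >= 1)
    withSeed(seed, {
        sizes <- sample(sizeRange[1L]:sizeRange[2L], nSets, replace = TRUE)
        sets <- lapply(sizes, function(sz) sort(sample(genes, sz)))
        names(sets) <- sprintf("SET%03d", seq_len(nSets))
        attr(sets, "description") <-
            setNames(sprintf("synthetic gene set %d", seq_len(nSets)),
                     names(sets))
        class(sets) <- c("geneSetCollection", "list")
        sets
    })
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of gene vectors.
#' @param path destination GMT file.
#' @export
writeGmt <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a simulated experiment as pipeline input files
#'
#' Emits exactly the three plate input files the readers consume
#' (`counts.csv`, `annotation.csv`, `metadata.csv`) plus a machine-readable
#' `truth.json` with the planted ground truth, into `dir`.
#'
#' @param sim result of [simulatePlates()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four written paths.
#' @export
writeSimulatedInputs <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    x <- sim$experiment
    ct <- ctValues(x)
    rownames(ct) <- rowData(x)$well
    paths <- c(counts = file.path(dir, "counts.csv"),
               annotation = file.path(dir, "annotation.csv"),
               metadata = file.path(dir, "metadata.csv"),
               truth = file.path(dir, "truth.json"))
    writeCtTable(ct, paths[["counts"]])
    writeWellAnnotation(rowData(x), paths[["annotation"]])
    writeSampleSheet(sim$samples, paths[["metadata"]])
    truth <- sim$truth
    truth$effects <- as.list(truth$effects)
    truth$shifts <- as.list(truth$shifts)
    truth$scenario <- unclass(truth$scenario)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
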