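#' @include AllClasses.R
NULL

#' Accessors for Ct experiments
#'
#' `ctValues()` returns the raw Ct matrix (cycles; `NA` = not detected),
#' `missingMask()` the logical not-detected mask, `wellInfo()` the well
#' annotation, `wellRoles()` the per-well role vector, `assayIds()` the
#' per-well assay names and `sampleGroups()` the named group labels.
#'
#' @param x a [CtExperiment-class] (or, where noted, a
#'   [NormalizedCtExperiment-class])
#' @return matrix, DataFrame or named vector as described above.
#' @name ct-accessors
#' @aliases ctValues missingMask wellInfo wellRoles assayIds sampleGroups
#' @examples
#' sim <- simulatePlates(simulationScenario(seed = 1))
#' dim(ctValues(sim$experiment))
#' table(wellRoles(sim$experiment))
NULL

#' @rdname ct-accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname ct-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname ct-accessors
#' @export
setGeneric("wellInfo", function(x) standardGeneric("wellInfo"))

#' @rdname ct-accessors
#' @export
setGeneric("wellRoles", function(x) standardGeneric("wellRoles"))

#' @rdname ct-accessors
#' @export
setGeneric("assayIds", function(x) standardGeneric("assayIds"))

#' @rdname ct-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ct-accessors
#' @export
setMethod("ctValues", "CtExperiment", function(x) assay(x, "ct"))

#' @rdname ct-accessors
#' @export
setMethod("missingMask", "CtExperiment", function(x) is.na(assay(x, "ct")))

#' @rdname ct-accessors
#' @export
setMethod("wellInfo", "CtExperiment", function(x) rowData(x))

#' @rdname ct-accessors
#' @export
setMethod("wellRoles", "CtExperiment",
          function(x) setNames(as.character(rowData(x)$role), rownames(x)))

#' @rdname ct-accessors
#' @export
setMethod("assayIds", "CtExperiment",
          function(x) setNames(as.character(rowData(x)$assay), rownames(x)))

#' @rdname ct-accessors
#' @export
setMethod("sampleGroups", "CtExperiment",
          function(x) setNames(as.character(colData(x)$group), colnames(x)))

#' @rdname ct-accessors
#' @export
setMethod("sampleGroups", "NormalizedCtExperiment",
          function(x) setNames(as.character(colData(x)$group), colnames(x)))

#' Per-sample reference Ct of a normalized experiment
#'
#' The mean control Ct (cycles) subtracted from each sample during
#' normalization; see [normalizeCt()].
#'
#' @param x a [NormalizedCtExperiment-class]
#' @return named numeric vector, one value per sample.
#' @export
setGeneric("sampleReference", function(x) standardGeneric("sampleReference"))

#' @rdname sampleReference
#' @export
setMethod("sampleReference", "NormalizedCtExperiment",
          function(x) setNames(colData(x)$referenceCt, colnames(x)))

setMethod("show", "CtExperiment", function(object) {
    cat("CtExperiment:", nrow(object), "wells x", ncol(object), "samples\n")
    rc <- table(factor(rowData(object)$role, levels = .WELL_ROLES))
    cat("  roles:", paste(names(rc), rc, sep = "=", collapse = " "), "\n")
    cat("  plates:", paste(unique(rowData(object)$plate), collapse = ", "),
        "\n")
    grp <- table(colData(object)$group, useNA = "ifany")
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
    cat("  not detected:", sum(is.na(assay(object, "ct"))), "cells\n")
    invisible(NULL)
})

setMethod("show", "NormalizedCtExperiment", function(object) {
    cat("NormalizedCtExperiment:", nrow(object), "miRNAs x", ncol(object),
        "samples (-deltaCt, log2 scale)\n")
    ref <- colData(object)$referenceCt
    cat("  reference Ct range:",
        paste(sprintf("%.2f", range(ref)), collapse = " - "), "cycles\n")
    invisible(NULL)
})
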