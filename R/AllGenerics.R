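#' Accessors for PullbackPatterns classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("mufrValues", function(object) standardGeneric("mufrValues"))
#' @rdname accessors
#' @export
setGeneric("mldValues", function(object) standardGeneric("mldValues"))
#' @rdname accessors
#' @export
setGeneric("rvdValues", function(object) standardGeneric("rvdValues"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setGeneric("pullbackCurve", function(object) standardGeneric("pullbackCurve"))
#' @rdname accessors
#' @export
setGeneric("distalMufr", function(object) standardGeneric("distalMufr"))
#' @rdname accessors
#' @export
setGeneric("patternLabel", function(object) standardGeneric("patternLabel"))
#' @rdname accessors
#' @export
setGeneric("vesselRecords", function(object) standardGeneric("vesselRecords"))
#' @rdname accessors
#' @export
setGeneric("patientCovariates",
           function(object) standardGeneric("patientCovariates"))
#' @rdname accessors
#' @export
setGeneric("ppgiValue", function(object) standardGeneric("ppgiValue"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("iterationMetrics",
           function(object) standardGeneric("iterationMetrics"))
#' @rdname accessors
#' @export
setGeneric("summaryTable", function(object) standardGeneric("summaryTable"))
#' @rdname accessors
#' @export
setGeneric("scoreVariances", function(object) standardGeneric("scoreVariances"))

#' @rdname accessors
setMethod("positions", "PullbackCurve", function(object) object@positions)
#' @rdname accessors
setMethod("mufrValues", "PullbackCurve", function(object) object@mufr)
#' @rdname accessors
setMethod("mldValues", "PullbackCurve", function(object) object@mld)
#' @rdname accessors
setMethod("rvdValues", "PullbackCurve", function(object) object@rvd)
#' @rdname accessors
setMethod("gridSpacing", "PullbackCurve",
          function(object) mean(diff(object@positions)))
#' @rdname accessors
setMethod("totalLength", "PullbackCurve", function(object) {
  p <- object@positions
  p[length(p)] - p[1L]
})

#' @rdname accessors
setMethod("pullbackCurve", "VesselRecord", function(object) object@curve)
#' @rdname accessors
setMethod("distalMufr", "VesselRecord", function(object) object@distalMufr)
#' @rdname accessors
setMethod("patternLabel", "VesselRecord", function(object) {
  if (length(object@label)) object@label else NA_character_
})

#' @rdname accessors
setMethod("vesselRecords", "VesselCohort", function(object) object@records)
#' @rdname accessors
setMethod("patientCovariates", "VesselCohort",
          function(object) object@covariates)
#' @rdname accessors
setMethod("patternLabel", "VesselCohort",
          function(object) object@covariates$label)

#' @rdname accessors
setMethod("ppgiValue", "PpgiComponents", function(object) object@ppgi)

#' @rdname accessors
setMethod("confusionCounts", "ConfusionMatrix", function(object) object@counts)

#' @rdname accessors
setMethod("iterationMetrics", "EvaluationReport",
          function(object) object@iterations)
#' @rdname accessors
setMethod("summaryTable", "EvaluationReport",
          function(object) object@summaryTable)

#' @rdname accessors
setMethod("scoreVariances", "MFPCAModel",
          function(object) object@multiEigenvalues)

## show methods -------------------------------------------------------------

setMethod("show", "PullbackCurve", function(object) {
  cat(sprintf("PullbackCurve: %d points, %.2f mm, spacing %.3g mm\n",
              length(object@positions), totalLength(object),
              gridSpacing(object)))
  cat(sprintf("  muFR %.3f (proximal) -> %.3f (distal)%s\n",
              object@mufr[1L], object@mufr[length(object@mufr)],
              if (length(object@mld)) ", with diameter curves" else ""))
})

setMethod("show", "VesselRecord", function(object) {
  cat(sprintf("VesselRecord %s (patient %s): distal muFR %.3f, RVD %.2f mm, label %s\n",
              object@vesselId, object@patientId, object@distalMufr,
              object@referenceDiameter, patternLabel(object)))
})

setMethod("show", "PpgiComponents", function(object) {
  cat(sprintf(
    "PPGi %.3f  [max 20-mm drop %.3f / vessel drop %.3f; diseased %.1f of %.1f mm]\n",
    object@ppgi, object@maxPpg20mm, object@deltaMufrVessel,
    object@diseaseLengthMm, object@totalLengthMm))
})

setMethod("show", "VesselCohort", function(object) {
  tab <- table(factor(object@covariates$label, levels = PATTERN_LEVELS))
  cat(sprintf("VesselCohort: %d vessels (%s)\n", length(object@records),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "FunctionalSample", function(object) {
  cat(sprintf("FunctionalSample: %d subjects, %d grid points, variables: %s\n",
              length(object@vesselIds), length(object@grid),
              paste(names(object@values), collapse = ", ")))
})

setMethod("show", "MFPCAModel", function(object) {
  cat(sprintf("MFPCAModel: %d components over %s; eigenvalues %s\n",
              object@nComponents, paste(object@variables, collapse = " + "),
              paste(signif(object@multiEigenvalues, 3), collapse = ", ")))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s [%s], classes %s\n", object@algorithm,
              object@task, paste(object@classLevels, collapse = "/")))
  if (!is.na(object@selectedLambda))
    cat(sprintf("  alpha %.2f, selected lambda %.4g\n",
                object@alpha, object@selectedLambda))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth):\n")
  print(object@counts)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %s / %s, %d iterations (%d re-drawn)\n",
              object@task, object@method, object@nIterations,
              object@redraws))
  print(object@summaryTable, row.names = FALSE, digits = 3)
})
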