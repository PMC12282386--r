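#' @import methods
NULL

#' Recognized physiological disease patterns
#'
#' The four qualitative physiological patterns of coronary artery disease:
#' focal (single short abrupt pressure drop), diffuse (gradual vessel-wide
#' decline), mixed (focal drop superimposed on diffuse decline) and serial
#' (two or more focal drops separated by >20 mm of non-diseased segment).
#'
#' @export
PATTERN_LEVELS <- c("focal", "diffuse", "mixed", "serial")

.POSITION_TOL <- 1e-6

## ---------------------------------------------------------------------------
## PullbackCurve
## ---------------------------------------------------------------------------

#' PullbackCurve: a virtual pullback trace on a uniform grid
#'
#' Holds the muFR (Murray's law-based quantitative flow ratio) values of one
#' vessel sampled at a constant along-vessel spacing (default 0.35 mm),
#' optionally together with co-registered lumen-diameter curves (minimal
#' lumen diameter and reference vessel diameter).
#'
#' @slot positions numeric, distance from the ostium in mm, strictly
#'   increasing with constant spacing.
#' @slot mufr numeric in [0, 1], one value per position.
#' @slot mld numeric, minimal lumen diameter in mm (length 0 when absent).
#' @slot rvd numeric, reference vessel diameter in mm (length 0 when absent).
#' @name PullbackCurve-class
#' @exportClass PullbackCurve
setClass("PullbackCurve",
  representation(positions = "numeric", mufr = "numeric",
                 mld = "numeric", rvd = "numeric"))

setValidity("PullbackCurve", function(object) {
  p <- object@positions
  v <- object@mufr
  if (length(p) < 2L) return("curve needs at least 2 points")
  if (length(v) != length(p)) return("mufr and positions lengths differ")
  d <- diff(p)
  if (any(d <= 0)) return("positions must be strictly increasing")
  if (max(d) - min(d) > .POSITION_TOL * max(d))
    return("positions must be uniformly spaced")
  if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12))
    return("mufr values must lie in [0, 1]")
  for (nm in c("mld", "rvd")) {
    dv <- slot(object, nm)
    if (length(dv) && length(dv) != length(p))
      return(sprintf("%s length differs from positions", nm))
    if (length(dv) && (anyNA(dv) || any(dv <= 0)))
      return(sprintf("%s diameters must be > 0", nm))
  }
  if (p[length(p)] - p[1L] <= 0) return("total length must be > 0")
  TRUE
})

#' Construct a PullbackCurve
#'
#' @param positions numeric, strictly increasing, constant spacing (mm).
#' @param mufr numeric in [0, 1].
#' @param mld,rvd optional diameter curves (mm), same length as positions.
#' @return a \linkS4class{PullbackCurve}.
#' @examples
#' crv <- PullbackCurve(seq(0, 7, by = 0.35), seq(1, 0.8, length.out = 21))
#' totalLength(crv)
#' @export
PullbackCurve <- function(positions, mufr, mld = numeric(), rvd = numeric()) {
  new("PullbackCurve", positions = as.numeric(positions),
      mufr = pmin(pmax(as.numeric(mufr), 0), 1),
      mld = as.numeric(mld), rvd = as.numeric(rvd))
}

## ---------------------------------------------------------------------------
## VesselRecord
## ---------------------------------------------------------------------------

#' VesselRecord: one interrogated vessel
#'
#' A pullback curve plus the vessel-level quantities used downstream: the
#' distal muFR (the last value of the trace), the proximal reference
#' diameter from quantitative coronary analysis, and the adjudicated
#' pattern label when available.
#'
#' @slot vesselId,patientId character identifiers.
#' @slot curve a \linkS4class{PullbackCurve}.
#' @slot distalMufr numeric, must equal the last curve value (tol 1e-9).
#' @slot referenceDiameter numeric, mm.
#' @slot label character, one of \code{PATTERN_LEVELS}, or length 0.
#' @name VesselRecord-class
#' @exportClass VesselRecord
setClass("VesselRecord",
  representation(vesselId = "character", patientId = "character",
                 curve = "PullbackCurve", distalMufr = "numeric",
                 referenceDiameter = "numeric", label = "character"))

setValidity("VesselRecord", function(object) {
  v <- object@curve@mufr
  if (abs(object@distalMufr - v[length(v)]) > 1e-9)
    return("distalMufr must equal the last curve value (tol 1e-9)")
  if (length(object@label) &&
      !object@label %in% PATTERN_LEVELS)
    return(sprintf("label must be one of: %s",
                   paste(PATTERN_LEVELS, collapse = ", ")))
  if (object@referenceDiameter <= 0) return("referenceDiameter must be > 0")
  TRUE
})

#' Construct a VesselRecord
#'
#' @param vesselId,patientId identifiers.
#' @param curve a \linkS4class{PullbackCurve}.
#' @param referenceDiameter proximal reference vessel diameter (mm).
#' @param distalMufr distal muFR; defaults to the last curve value.
#' @param label optional pattern label (see \code{\link{PATTERN_LEVELS}}).
#' @return a \linkS4class{VesselRecord}.
#' @export
VesselRecord <- function(vesselId, patientId, curve, referenceDiameter,
                         distalMufr = NULL, label = character()) {
  v <- curve@mufr
  if (is.null(distalMufr)) distalMufr <- v[length(v)]
  if (length(label) && is.na(label)) label <- character()
  new("VesselRecord", vesselId = as.character(vesselId),
      patientId = as.character(patientId), curve = curve,
      distalMufr = as.numeric(distalMufr),
      referenceDiameter = as.numeric(referenceDiameter),
      label = as.character(label))
}

## ---------------------------------------------------------------------------
## PpgiComponents
## ---------------------------------------------------------------------------

#' PpgiComponents: the terms of the pullback pressure gradient index
#'
#' PPGi = (maxPpg20mm / deltaMufrVessel +
#'         (1 - diseaseLengthMm / totalLengthMm)) / 2.
#' Values near 1 indicate focal disease, near 0 diffuse disease.
#'
#' @slot maxPpg20mm largest muFR drop over any 20-mm window.
#' @slot deltaMufrVessel proximal-minus-distal muFR drop.
#' @slot diseaseLengthMm total length with functional disease (mm).
#' @slot totalLengthMm interrogated vessel length (mm).
#' @slot ppgi the index in [0, 1].
#' @name PpgiComponents-class
#' @exportClass PpgiComponents
setClass("PpgiComponents",
  representation(maxPpg20mm = "numeric", deltaMufrVessel = "numeric",
                 diseaseLengthMm = "numeric", totalLengthMm = "numeric",
                 ppgi = "numeric"))

setValidity("PpgiComponents", function(object) {
  if (object@deltaMufrVessel <= 0) return("deltaMufrVessel must be > 0")
  if (object@maxPpg20mm < 0) return("maxPpg20mm must be >= 0")
  if (object@diseaseLengthMm < 0 ||
      object@diseaseLengthMm > object@totalLengthMm + 1e-9)
    return("diseaseLengthMm must lie in [0, totalLengthMm]")
  expect <- (object@maxPpg20mm / object@deltaMufrVessel +
             (1 - object@diseaseLengthMm / object@totalLengthMm)) / 2
  if (abs(expect - object@ppgi) > 1e-12)
    return("ppgi does not equal its defining formula")
  TRUE
})

## ---------------------------------------------------------------------------
## PatternParams
## ---------------------------------------------------------------------------

#' PatternParams: generative description of one synthetic vessel
#'
#' Describes a vessel as a set of sigmoidal focal pressure drops (position,
#' depth, width) plus an optional linear diffuse decline, with smooth noise
#' and a linearly tapering reference diameter. The class-specific
#' constraints mirror the field's consensus definitions: a focal lesion is
#' an abrupt drop (>= 0.05) within <= 20 mm; serial lesions are >= 2 focal
#' drops separated by > 20 mm of non-diseased segment; diffuse disease has
#' no discrete lesion but a positive vessel-wide slope; a mixed pattern has
#' both.
#'
#' @slot pattern one of \code{PATTERN_LEVELS}.
#' @slot vesselLength total interrogated length (mm).
#' @slot lesionPositions,lesionDrops,lesionWidths per-lesion center (mm),
#'   muFR drop (unitless), and width (mm; the distance containing 90\% of
#'   the drop).
#' @slot diffuseSlope linear muFR decline (per mm, >= 0).
#' @slot noiseSd standard deviation of the smooth trace noise.
#' @slot taperRate linear reference-diameter taper (mm per mm).
#' @slot proximalDiameter reference diameter at the ostium (mm).
#' @name PatternParams-class
#' @exportClass PatternParams
setClass("PatternParams",
  representation(pattern = "character", vesselLength = "numeric",
                 lesionPositions = "numeric", lesionDrops = "numeric",
                 lesionWidths = "numeric", diffuseSlope = "numeric",
                 noiseSd = "numeric", taperRate = "numeric",
                 proximalDiameter = "numeric"))

setValidity("PatternParams", function(object) {
  if (!object@pattern %in% PATTERN_LEVELS)
    return("unknown pattern")
  L <- object@vesselLength
  if (L <= 0) return("vesselLength must be > 0")
  k <- length(object@lesionPositions)
  if (length(object@lesionDrops) != k || length(object@lesionWidths) != k)
    return("lesion vectors must have equal length")
  if (k && (any(object@lesionDrops <= 0) || any(object@lesionWidths <= 0)))
    return("lesion drops and widths must be > 0")
  if (k && any(object@lesionPositions < 0 | object@lesionPositions > L))
    return("lesion positions must lie inside the vessel")
  if (object@diffuseSlope < 0) return("diffuseSlope must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@taperRate < 0) return("taperRate must be >= 0")
  if (object@proximalDiameter <= 0) return("proximalDiameter must be > 0")
  pat <- object@pattern
  if (pat == "focal") {
    if (k != 1L) return("focal pattern requires exactly one lesion")
    if (object@lesionWidths[1L] > 20) return("focal lesion width must be <= 20 mm")
    if (object@lesionDrops[1L] < 0.05) return("focal lesion drop must be >= 0.05")
  } else if (pat == "serial") {
    if (k < 2L) return("serial pattern requires >= 2 lesions")
    if (any(object@lesionWidths > 20)) return("serial lesion widths must be <= 20 mm")
    o <- order(object@lesionPositions)
    lo <- object@lesionPositions[o] - object@lesionWidths[o] / 2
    hi <- object@lesionPositions[o] + object@lesionWidths[o] / 2
    gaps <- lo[-1L] - hi[-k]
    if (any(gaps <= 20))
      return("serial lesions must be separated by > 20 mm of healthy segment")
  } else if (pat == "diffuse") {
    if (k != 0L) return("diffuse pattern must have no discrete lesion")
    if (object@diffuseSlope <= 0) return("diffuse pattern requires diffuseSlope > 0")
  } else if (pat == "mixed") {
    if (k < 1L) return("mixed pattern requires >= 1 lesion")
    if (object@diffuseSlope <= 0) return("mixed pattern requires diffuseSlope > 0")
  }
  TRUE
})

#' Construct PatternParams
#'
#' @param pattern one of \code{PATTERN_LEVELS}.
#' @param vesselLength vessel length in mm.
#' @param lesionPositions,lesionDrops,lesionWidths per-lesion parameters.
#' @param diffuseSlope linear decline per mm.
#' @param noiseSd smooth-noise standard deviation (default 0.005).
#' @param taperRate diameter taper per mm (default 0.008).
#' @param proximalDiameter proximal reference diameter in mm (default 3.61,
#'   the cohort mean).
#' @return a \linkS4class{PatternParams}.
#' @examples
#' patternParams("focal", 80, lesionPositions = 40,
#'               lesionDrops = 0.3, lesionWidths = 7)
#' @export
patternParams <- function(pattern, vesselLength,
                          lesionPositions = numeric(),
                          lesionDrops = numeric(),
                          lesionWidths = numeric(),
                          diffuseSlope = 0, noiseSd = 0.005,
                          taperRate = 0.008, proximalDiameter = 3.61) {
  new("PatternParams", pattern = pattern,
      vesselLength = as.numeric(vesselLength),
      lesionPositions = as.numeric(lesionPositions),
      lesionDrops = as.numeric(lesionDrops),
      lesionWidths = as.numeric(lesionWidths),
      diffuseSlope = as.numeric(diffuseSlope),
      noiseSd = as.numeric(noiseSd), taperRate = as.numeric(taperRate),
      proximalDiameter = as.numeric(proximalDiameter))
}

## ---------------------------------------------------------------------------
## VesselCohort
## ---------------------------------------------------------------------------

#' VesselCohort: vessels plus patient covariates
#'
#' @slot records list of \linkS4class{VesselRecord}.
#' @slot covariates data.frame with one row per vessel: vessel_id,
#'   patient_id, age, sex, smoking, hypertension, diabetes, dyslipidaemia,
#'   reference_diameter, label.
#' @name VesselCohort-class
#' @exportClass VesselCohort
setClass("VesselCohort",
  representation(records = "list", covariates = "data.frame"))

setValidity("VesselCohort", function(object) {
  if (!all(vapply(object@records, is, logical(1), "VesselRecord")))
    return("records must all be VesselRecord objects")
  if (nrow(object@covariates) != length(object@records))
    return("covariates must have one row per vessel")
  need <- c("vessel_id", "patient_id", "age", "sex", "smoking",
            "hypertension", "diabetes", "dyslipidaemia",
            "reference_diameter", "label")
  miss <- setdiff(need, names(object@covariates))
  if (length(miss))
    return(paste("covariates missing columns:", paste(miss, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## FunctionalSample
## ---------------------------------------------------------------------------

#' FunctionalSample: registered multivariate functional data
#'
#' Curves of all vessels registered onto a common normalized grid in
#' [0, 1], one value matrix (subjects x grid points) per variable.
#'
#' @slot grid numeric, strictly increasing, typically spanning [0, 1].
#' @slot values named list of numeric matrices (subjects x G).
#' @slot vesselIds character, row identities shared by all matrices.
#' @name FunctionalSample-class
#' @exportClass FunctionalSample
setClass("FunctionalSample",
  representation(grid = "numeric", values = "list", vesselIds = "character"))

setValidity("FunctionalSample", function(object) {
  if (length(object@grid) < 2L || any(diff(object@grid) <= 0))
    return("grid must be strictly increasing with >= 2 points")
  if (!length(object@values)) return("at least one variable required")
  if (is.null(names(object@values)) || any(!nzchar(names(object@values))))
    return("values must be a named list")
  for (nm in names(object@values)) {
    m <- object@values[[nm]]
    if (!is.matrix(m) || ncol(m) != length(object@grid))
      return(sprintf("variable '%s' must be a matrix with G columns", nm))
    if (anyNA(m)) return(sprintf("variable '%s' contains missing values", nm))
    if (nrow(m) != length(object@vesselIds))
      return(sprintf("variable '%s' row count differs from vesselIds", nm))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## MFPCAModel
## ---------------------------------------------------------------------------

#' MFPCAModel: fitted multivariate functional PCA
#'
#' Mean functions and univariate eigendecompositions per variable, the
#' score-combination matrix mapping stacked univariate scores to
#' multivariate scores, and the multivariate eigenvalues.
#'
#' @slot grid common grid.
#' @slot weights quadrature weights on the grid.
#' @slot variables variable names, in block order.
#' @slot meanFunctions named list of numeric vectors (length G).
#' @slot uniEigenfunctions named list of G x m_j matrices.
#' @slot uniEigenvalues named list of numeric vectors.
#' @slot combinationMatrix M x K matrix (M = sum of m_j).
#' @slot multiEigenvalues numeric, length K, non-negative non-increasing.
#' @slot nComponents integer K.
#' @name MFPCAModel-class
#' @exportClass MFPCAModel
setClass("MFPCAModel",
  representation(grid = "numeric", weights = "numeric",
                 variables = "character", meanFunctions = "list",
                 uniEigenfunctions = "list", uniEigenvalues = "list",
                 combinationMatrix = "matrix", multiEigenvalues = "numeric",
                 nComponents = "integer"))

setValidity("MFPCAModel", function(object) {
  ev <- object@multiEigenvalues
  if (any(ev < -1e-10)) return("multivariate eigenvalues must be >= 0")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-10))
    return("multivariate eigenvalues must be non-increasing")
  if (ncol(object@combinationMatrix) != object@nComponents)
    return("combinationMatrix columns must equal nComponents")
  TRUE
})

## ---------------------------------------------------------------------------
## FitResult
## ---------------------------------------------------------------------------

#' FitResult: a fitted classifier
#'
#' @slot algorithm "penalized_logistic" or "random_forest".
#' @slot task task identifier (free text; e.g. "focal_vs_diffuse").
#' @slot classLevels class labels, fixed column order for probabilities.
#' @slot featureNames training feature columns, fixed order.
#' @slot fit the underlying fitted object (cv.glmnet or randomForest).
#' @slot standardization list with feature means and sds.
#' @slot selectedLambda chosen penalty (NA for random forest).
#' @slot alpha elastic-net mixing (NA for random forest).
#' @slot cvPath data.frame of the cross-validated penalty path (or empty).
#' @name FitResult-class
#' @exportClass FitResult
setClass("FitResult",
  representation(algorithm = "character", task = "character",
                 classLevels = "character", featureNames = "character",
                 fit = "ANY", standardization = "list",
                 selectedLambda = "numeric", alpha = "numeric",
                 cvPath = "data.frame"))

## ---------------------------------------------------------------------------
## ConfusionMatrix
## ---------------------------------------------------------------------------

#' ConfusionMatrix: truth-by-prediction counts
#'
#' Rows are the adjudicated truth, columns the predicted class.
#'
#' @slot counts k x k non-negative integer matrix.
#' @slot classOrder class labels (row and column order).
#' @name ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", classOrder = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  if (length(object@classOrder) != nrow(m))
    return("classOrder length must match matrix dimension")
  TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param counts square numeric matrix of non-negative integers, rows =
#'   truth, columns = prediction.
#' @param classOrder class labels.
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrix <- function(counts, classOrder = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(classOrder)) classOrder <- as.character(seq_len(nrow(counts)))
  dimnames(counts) <- list(truth = classOrder, predicted = classOrder)
  new("ConfusionMatrix", counts = counts, classOrder = as.character(classOrder))
}

## ---------------------------------------------------------------------------
## EvaluationReport
## ---------------------------------------------------------------------------

#' EvaluationReport: repeated-split evaluation summary
#'
#' @slot task,method identifiers of what was evaluated.
#' @slot iterations data.frame, one row per split, one column per metric.
#' @slot summaryTable data.frame with mean and 95\% CI per metric.
#' @slot nIterations number of splits.
#' @slot baseSeed seed of the first iteration.
#' @slot redraws number of degenerate test sets that were re-drawn.
#' @name EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(task = "character", method = "character",
                 iterations = "data.frame", summaryTable = "data.frame",
                 nIterations = "integer", baseSeed = "integer",
                 redraws = "integer"))

setValidity("EvaluationReport", function(object) {
  s <- object@summaryTable
  if (nrow(s)) {
    ok <- is.na(s$mean) | (s$ci_lower <= s$mean + 1e-9 &
                           s$mean <= s$ci_upper + 1e-9)
    if (!all(ok)) return("summary CI must bracket the mean")
  }
  TRUE
})
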