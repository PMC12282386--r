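## Feature assembly.
##
## The muFR model uses 12 features: six demographic (age, sex, smoking,
## diabetes, dyslipidaemia, hypertension), three MFPCA scores, the
## reference diameter, the distal muFR and the maximum d muFR/ds. The PPGi
## model adds PPGi as a 13th feature. Smoking is a 3-level categorical
## encoded as two indicator contrasts against the "non"-smoker baseline,
## so the 12-feature vector has 13 numeric columns and the 13-feature
## vector has 14.

.FEATURE_COLUMNS <- c("age", "sex_male", "smoking_current",
                      "smoking_previous", "diabetes", "dyslipidaemia",
                      "hypertension", "score1", "score2", "score3",
                      "reference_diameter", "distal_mufr", "d_mufr_ds")

#' Assemble the classifier feature vector for one vessel
#'
#' Deterministic mapping to the fixed, documented feature order
#' (\code{age, sex_male, smoking_current, smoking_previous, diabetes,
#' dyslipidaemia, hypertension, score1..3, reference_diameter,
#' distal_mufr, d_mufr_ds[, ppgi]}). Encodings are fixed: sex male = 1;
#' smoking indicators contrast "current" and "previous" against the
#' "non" baseline. A missing covariate raises an error; nothing is
#' silently imputed.
#'
#' @param record a \linkS4class{VesselRecord}.
#' @param covariates one-row data.frame (or list) with \code{age, sex,
#'   smoking, hypertension, diabetes, dyslipidaemia}.
#' @param scores numeric length-3 MFPCA score vector.
#' @param includePpgi append PPGi as the final feature?
#' @param ppgi optional precomputed PPGi (computed from the curve when
#'   \code{NULL} and \code{includePpgi} is \code{TRUE}).
#' @param dMufrDs optional precomputed maximum local gradient.
#' @return named numeric vector with attribute \code{nFeatures} (12 or 13;
#'   the smoking indicator pair counts as one feature).
#' @export
assembleFeatures <- function(record, covariates, scores, includePpgi = FALSE,
                             ppgi = NULL, dMufrDs = NULL) {
  stopifnot(is(record, "VesselRecord"))
  covariates <- as.list(covariates)
  need <- c("age", "sex", "smoking", "hypertension", "diabetes",
            "dyslipidaemia")
  for (nm in need) {
    v <- covariates[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      .stopf("assembleFeatures: missing covariate '%s' (no silent imputation)", nm)
  }
  if (length(scores) != 3L || anyNA(scores))
    .stopf("assembleFeatures: exactly 3 MFPCA scores required")
  if (!covariates$sex %in% c("male", "female"))
    .stopf("assembleFeatures: sex must be 'male' or 'female'")
  if (!covariates$smoking %in% c("non", "current", "previous"))
    .stopf("assembleFeatures: smoking must be 'non', 'current' or 'previous'")
  if (is.null(dMufrDs)) dMufrDs <- maxLocalGradient(record@curve)
  out <- c(age = as.numeric(covariates$age),
           sex_male = as.numeric(covariates$sex == "male"),
           smoking_current = as.numeric(covariates$smoking == "current"),
           smoking_previous = as.numeric(covariates$smoking == "previous"),
           diabetes = as.numeric(as.logical(covariates$diabetes)),
           dyslipidaemia = as.numeric(as.logical(covariates$dyslipidaemia)),
           hypertension = as.numeric(as.logical(covariates$hypertension)),
           score1 = scores[1L], score2 = scores[2L], score3 = scores[3L],
           reference_diameter = record@referenceDiameter,
           distal_mufr = record@distalMufr,
           d_mufr_ds = dMufrDs)
  if (includePpgi) {
    if (is.null(ppgi)) ppgi <- ppgiValue(computePpgi(record@curve))
    out <- c(out, ppgi = ppgi)
  }
  structure(out, nFeatures = if (includePpgi) 13L else 12L)
}

#' Per-vessel physiological indices for a whole cohort
#'
#' Computes PPGi, the maximum local gradient and the vessel flags for
#' every record; vessels without functional disease (distal muFR > 0.95)
#' are flagged, not silently dropped.
#'
#' @param cohort a \linkS4class{VesselCohort}.
#' @param ... passed to \code{\link{computePpgi}}.
#' @return data.frame with one row per vessel.
#' @export
cohortIndices <- function(cohort, ...) {
  stopifnot(is(cohort, "VesselCohort"))
  rows <- lapply(vesselRecords(cohort), function(r) {
    fl <- vesselFlags(r)
    pc <- computePpgi(r@curve, ...)
    data.frame(vessel_id = r@vesselId,
               distal_mufr = r@distalMufr,
               ppgi = pc@ppgi,
               max_ppg_20mm = pc@maxPpg20mm,
               delta_mufr_vessel = pc@deltaMufrVessel,
               disease_length_mm = pc@diseaseLengthMm,
               total_length_mm = pc@totalLengthMm,
               d_mufr_ds = maxLocalGradient(r@curve),
               major_gradient = hasMajorGradient(maxLocalGradient(r@curve)),
               significant = fl$significant,
               no_functional_disease = fl$noFunctionalDisease,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature matrix for a cohort
#'
#' Binds the per-vessel feature vectors (see
#' \code{\link{assembleFeatures}}) into a numeric matrix in the fixed
#' column order.
#'
#' @param cohort a \linkS4class{VesselCohort}.
#' @param scores subjects x 3 MFPCA score matrix, rows aligned with the
#'   cohort's vessels.
#' @param includePpgi append the PPGi column?
#' @param indices optional precomputed \code{\link{cohortIndices}} table.
#' @return numeric matrix, one row per vessel.
#' @export
buildFeatureMatrix <- function(cohort, scores, includePpgi = FALSE,
                               indices = NULL) {
  stopifnot(is(cohort, "VesselCohort"))
  recs <- vesselRecords(cohort)
  cov <- cohort@covariates
  if (is.null(indices)) indices <- cohortIndices(cohort)
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(recs))
  rows <- lapply(seq_along(recs), function(i)
    assembleFeatures(recs[[i]], cov[i, , drop = FALSE], scores[i, ],
                     includePpgi = includePpgi,
                     ppgi = indices$ppgi[i], dMufrDs = indices$d_mufr_ds[i]))
  X <- do.call(rbind, rows)
  rownames(X) <- cov$vessel_id
  X
}
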