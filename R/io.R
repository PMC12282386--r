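## File interfaces.
##
## Curve file: long-format CSV with header vessel_id,position_mm,mufr,mld,rvd
## (mld/rvd may be empty), UTF-8, "." decimal separator. Positions are
## distances from the ostium in mm, 0-based at the proximal analysis start.
## Cohort file: one row per vessel with the patient covariates and label.

#' Write pullback curves to a long-format CSV
#'
#' @param x a \linkS4class{VesselCohort}, a list of
#'   \linkS4class{VesselRecord}, or a named list of
#'   \linkS4class{PullbackCurve}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePullbackCsv <- function(x, path) {
  if (is(x, "VesselCohort")) x <- vesselRecords(x)
  rows <- lapply(seq_along(x), function(i) {
    el <- x[[i]]
    if (is(el, "VesselRecord")) {
      id <- el@vesselId
      crv <- el@curve
    } else {
      id <- if (!is.null(names(x))) names(x)[i] else sprintf("V%03d", i)
      crv <- el
    }
    n <- length(crv@positions)
    data.frame(vessel_id = id, position_mm = crv@positions,
               mufr = crv@mufr,
               mld = if (length(crv@mld)) crv@mld else rep(NA_real_, n),
               rvd = if (length(crv@rvd)) crv@rvd else rep(NA_real_, n))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read pullback curves from a long-format CSV
#'
#' @param path CSV file with columns
#'   \code{vessel_id,position_mm,mufr,mld,rvd}.
#' @return named list of \linkS4class{PullbackCurve}, one per vessel, in
#'   file order.
#' @export
readPullbackCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "position_mm", "mufr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("readPullbackCsv: missing columns: %s", paste(miss, collapse = ", "))
  ids <- unique(df$vessel_id)
  out <- lapply(ids, function(id) {
    d <- df[df$vessel_id == id, ]
    d <- d[order(d$position_mm), ]
    mld <- if ("mld" %in% names(d) && !anyNA(d$mld)) d$mld else numeric()
    rvd <- if ("rvd" %in% names(d) && !anyNA(d$rvd)) d$rvd else numeric()
    PullbackCurve(d$position_mm, d$mufr, mld = mld, rvd = rvd)
  })
  names(out) <- ids
  out
}

#' Write the cohort covariate table
#'
#' @param cohort a \linkS4class{VesselCohort}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "VesselCohort"))
  utils::write.csv(cohort@covariates, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a VesselCohort from curve and covariate CSV files
#'
#' @param curvesPath long-format curve CSV (see
#'   \code{\link{readPullbackCsv}}).
#' @param cohortPath covariate CSV with columns
#'   \code{vessel_id,patient_id,age,sex,smoking,hypertension,diabetes,
#'   dyslipidaemia,reference_diameter,label}.
#' @return a \linkS4class{VesselCohort}.
#' @export
readCohortCsv <- function(curvesPath, cohortPath) {
  curves <- readPullbackCsv(curvesPath)
  cov <- utils::read.csv(cohortPath, stringsAsFactors = FALSE)
  miss <- setdiff(cov$vessel_id, names(curves))
  if (length(miss))
    .stopf("readCohortCsv: no curves for vessels: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  recs <- lapply(seq_len(nrow(cov)), function(i) {
    lab <- cov$label[i]
    VesselRecord(cov$vessel_id[i], cov$patient_id[i],
                 curves[[cov$vessel_id[i]]],
                 referenceDiameter = cov$reference_diameter[i],
                 label = if (is.na(lab) || !nzchar(lab)) character() else lab)
  })
  new("VesselCohort", records = recs, covariates = cov)
}

#' Serialize a fitted MFPCA model to JSON
#'
#' Stores grid, quadrature weights, means, univariate eigenpairs,
#' combination matrix and multivariate eigenvalues, so a model fitted by
#' \code{\link{fitMfpca}} can be reused between training and
#' classification runs.
#'
#' @param model an \linkS4class{MFPCAModel}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeMfpcaJson <- function(model, path) {
  stopifnot(is(model, "MFPCAModel"))
  obj <- list(grid = model@grid, weights = model@weights,
              variables = model@variables,
              meanFunctions = model@meanFunctions,
              uniEigenfunctions = model@uniEigenfunctions,
              uniEigenvalues = model@uniEigenvalues,
              combinationMatrix = model@combinationMatrix,
              multiEigenvalues = model@multiEigenvalues,
              nComponents = model@nComponents)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted MFPCA model from JSON
#'
#' @param path JSON file written by \code{\link{writeMfpcaJson}}.
#' @return an \linkS4class{MFPCAModel}.
#' @export
readMfpcaJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m) if (is.matrix(m)) m else matrix(unlist(m), nrow = length(m), byrow = TRUE)
  new("MFPCAModel", grid = obj$grid, weights = obj$weights,
      variables = obj$variables,
      meanFunctions = lapply(obj$meanFunctions, as.numeric),
      uniEigenfunctions = lapply(obj$uniEigenfunctions, asMat),
      uniEigenvalues = lapply(obj$uniEigenvalues, as.numeric),
      combinationMatrix = asMat(obj$combinationMatrix),
      multiEigenvalues = as.numeric(obj$multiEigenvalues),
      nComponents = as.integer(obj$nComponents))
}
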