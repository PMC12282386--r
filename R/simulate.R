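## Synthetic cohort generator.
##
## The generator replaces the study's (undeposited) angiographic data. A
## vessel is a muFR trace of 1.0 minus a sum of sigmoidal focal drops and a
## linear diffuse decline, with smooth correlated noise, sampled every
## 0.35 mm; lumen-diameter curves taper linearly with Gaussian-shaped
## narrowings under the lesions. Default parameter distributions were
## chosen once from the cohort's reported vessel and patient marginals
## (class mix 160/74/82/27; focal muFR 0.71 +/- 0.16; diffuse muFR
## 0.82 +/- 0.08; reference diameter 3.61 +/- 0.66 mm; class-conditional
## covariate tables).

.CLASS_PROBS <- c(focal = 160, diffuse = 74, mixed = 82, serial = 27) / 343

# Class-conditional covariate marginals (per-class proportions).
.COVARIATE_TABLE <- list(
  male = c(focal = 144 / 160, diffuse = 53 / 74, mixed = 61 / 82, serial = 25 / 27),
  smoking = list(  # non, current, previous
    focal = c(66, 71, 23) / 160, diffuse = c(42, 31, 1) / 74,
    mixed = c(34, 40, 8) / 82, serial = c(11, 12, 4) / 27),
  hypertension = c(focal = 95 / 160, diffuse = 60 / 74, mixed = 60 / 82, serial = 23 / 27),
  diabetes = c(focal = 25 / 160, diffuse = 18 / 74, mixed = 27 / 82, serial = 3 / 27),
  dyslipidaemia = c(focal = 103 / 160, diffuse = 53 / 74, mixed = 62 / 82, serial = 19 / 27),
  ageMean = c(focal = 58, diffuse = 68, mixed = 64, serial = 61),
  ageSd = c(focal = 13, diffuse = 11, mixed = 12, serial = 12))

.SIGMOID_SCALE <- 2 * log(19)  # width = distance containing 90% of the drop

# Cumulative drop profile at positions s, anchored so the profile is 0 at
# s = 0 (the proximal trace is normalized to muFR 1.0).
.dropProfile <- function(s, params) {
  out <- params@diffuseSlope * s
  k <- length(params@lesionPositions)
  for (i in seq_len(k)) {
    sc <- params@lesionWidths[i] / .SIGMOID_SCALE
    ci <- params@lesionPositions[i]
    out <- out + params@lesionDrops[i] *
      (stats::plogis((s - ci) / sc) - stats::plogis(-ci / sc))
  }
  out
}

# Build one vessel from validated params using the *current* RNG stream.
.buildVessel <- function(params, vesselId, patientId, spacing = 0.35) {
  L <- params@vesselLength
  n <- floor(L / spacing + 1e-9) + 1L
  s <- (seq_len(n) - 1L) * spacing

  drop <- .dropProfile(s, params)
  # Guarantee distal muFR <= 0.95 (margin for the excluded-vessel rule) and
  # keep the trace above ~0: rescale the whole drop profile when needed.
  distalDrop <- drop[n]
  if (distalDrop < 0.055) drop <- drop * (0.055 / max(distalDrop, 1e-12))
  if (max(drop) > 0.95) drop <- drop * (0.95 / max(drop))
  base <- 1 - drop

  mufr <- base
  if (params@noiseSd > 0) {
    eps <- .movingAverage(stats::rnorm(n), 9L)
    sde <- stats::sd(eps)
    if (is.finite(sde) && sde > 0) eps <- eps / sde * params@noiseSd
    # taper the noise envelope to zero over the first/last 3 mm so the
    # normalized proximal value (1.0) and the distal guarantee survive
    env <- pmin(1, pmin(s, L - s) / 3)
    mufr <- pmin(pmax(base + eps * env, 0), 1)
  }

  # Diameter curves: linear taper, Gaussian narrowings under the lesions,
  # a uniform narrowing for the diffuse component.
  rvd <- pmax(params@proximalDiameter - params@taperRate * s, 0.8)
  sten <- rep(min(0.4, 2 * params@diffuseSlope * L), n)
  for (i in seq_along(params@lesionPositions)) {
    amp <- min(0.85, 0.30 + 0.9 * params@lesionDrops[i])
    sig <- params@lesionWidths[i] / 3
    sten <- sten + amp * exp(-(s - params@lesionPositions[i])^2 / (2 * sig^2))
  }
  mld <- rvd * (1 - pmin(sten, 0.92))

  curve <- PullbackCurve(s, mufr, mld = mld, rvd = rvd)
  VesselRecord(vesselId, patientId, curve,
               referenceDiameter = params@proximalDiameter,
               label = params@pattern)
}

#' Simulate one synthetic vessel
#'
#' Deterministic given seed and parameters. The muFR trace is 1.0 minus
#' the sum of sigmoidal lesion drops and the linear diffuse decline, plus
#' smooth bounded noise, clipped to [0, 1] and sampled every
#' \code{spacing} mm; a distal muFR of at most 0.95 is guaranteed by
#' construction (the drop profile is rescaled when necessary). Diameter
#' curves taper linearly with narrowings under the lesions.
#'
#' @param params a valid \linkS4class{PatternParams}.
#' @param seed integer RNG seed.
#' @param vesselId,patientId identifiers.
#' @param spacing sampling step in mm (default 0.35).
#' @return a labelled \linkS4class{VesselRecord}.
#' @examples
#' p <- patternParams("focal", 80, lesionPositions = 40,
#'                    lesionDrops = 0.3, lesionWidths = 7, noiseSd = 0)
#' rec <- simulateVessel(p, seed = 1)
#' ppgiValue(computePpgi(pullbackCurve(rec)))
#' @export
simulateVessel <- function(params, seed, vesselId = "V1", patientId = "P1",
                           spacing = 0.35) {
  stopifnot(is(params, "PatternParams"))
  validObject(params)
  .withSeed(seed, .buildVessel(params, vesselId, patientId, spacing))
}

# Draw class-typical PatternParams using the current RNG stream.
.randomPatternParams <- function(pattern) {
  L <- stats::runif(1, 40, 120)
  taper <- stats::runif(1, 0.004, 0.012)
  d0 <- .rtruncnorm(1, 3.61, 0.66, 2.0, 6.0)
  noise <- 0.005
  if (pattern == "focal") {
    patternParams("focal", L,
                  lesionPositions = stats::runif(1, 0.15 * L, 0.85 * L),
                  lesionDrops = .rtruncnorm(1, 0.29, 0.16, 0.05, 0.70),
                  lesionWidths = stats::runif(1, 4, 18),
                  diffuseSlope = stats::runif(1, 0, 0.0008),  # sub-threshold taper
                  noiseSd = noise, taperRate = taper, proximalDiameter = d0)
  } else if (pattern == "diffuse") {
    patternParams("diffuse", L,
                  diffuseSlope = .rtruncnorm(1, 0.18, 0.08, 0.06, 0.50) / L,
                  noiseSd = noise, taperRate = taper, proximalDiameter = d0)
  } else if (pattern == "mixed") {
    patternParams("mixed", L,
                  lesionPositions = stats::runif(1, 0.15 * L, 0.85 * L),
                  lesionDrops = .rtruncnorm(1, 0.20, 0.10, 0.05, 0.50),
                  lesionWidths = stats::runif(1, 4, 18),
                  diffuseSlope = .rtruncnorm(1, 0.12, 0.05, 0.04, 0.30) / L,
                  noiseSd = noise, taperRate = taper, proximalDiameter = d0)
  } else {  # serial
    w <- stats::runif(2, 4, 12)
    # two focal drops separated by > 20 mm of healthy segment
    minSpan <- sum(w) / 2 + 21
    c1 <- stats::runif(1, 0.1 * L, max(0.1 * L + 1e-6, 0.85 * L - minSpan))
    c2 <- c1 + minSpan + stats::runif(1, 0, max(0, 0.9 * L - c1 - minSpan))
    patternParams("serial", L,
                  lesionPositions = c(c1, c2),
                  lesionDrops = .rtruncnorm(2, 0.16, 0.08, 0.05, 0.40),
                  lesionWidths = w,
                  noiseSd = noise, taperRate = taper, proximalDiameter = d0)
  }
}

.drawCovariates <- function(pattern) {
  ct <- .COVARIATE_TABLE
  smok <- sample(c("non", "current", "previous"), 1,
                 prob = ct$smoking[[pattern]])
  data.frame(
    age = round(.rtruncnorm(1, ct$ageMean[[pattern]], ct$ageSd[[pattern]], 18, 100)),
    sex = if (stats::runif(1) < ct$male[[pattern]]) "male" else "female",
    smoking = smok,
    hypertension = stats::runif(1) < ct$hypertension[[pattern]],
    diabetes = stats::runif(1) < ct$diabetes[[pattern]],
    dyslipidaemia = stats::runif(1) < ct$dyslipidaemia[[pattern]],
    stringsAsFactors = FALSE)
}

#' Simulate a labelled synthetic cohort
#'
#' Vessels are drawn i.i.d. with pattern classes at \code{classProbs}
#' (default: the 160/74/82/27 focal/diffuse/mixed/serial mix of the
#' reference cohort) with class-typical curve morphology, and patient
#' covariates from class-conditional marginals (diffuse patients older,
#' etc.). Identical seeds yield identical cohorts.
#'
#' @param nVessels number of vessels (>= 0).
#' @param classProbs named 4-simplex over
#'   \code{c("focal","diffuse","mixed","serial")}.
#' @param seed integer RNG seed.
#' @param noiseSd trace noise level passed to every vessel (default 0.005).
#' @return a \linkS4class{VesselCohort}.
#' @examples
#' coh <- simulateCohort(20, seed = 1)
#' table(patternLabel(coh))
#' @export
simulateCohort <- function(nVessels, classProbs = .CLASS_PROBS, seed = 1,
                           noiseSd = 0.005) {
  if (nVessels < 0) .stopf("simulateCohort: nVessels must be >= 0")
  if (noiseSd < 0) .stopf("simulateCohort: noiseSd must be >= 0")
  classProbs <- classProbs[PATTERN_LEVELS]
  if (anyNA(classProbs) || any(classProbs < 0) ||
      abs(sum(classProbs) - 1) > 1e-8)
    .stopf("simulateCohort: classProbs must be a named simplex over the four patterns")
  .withSeed(seed, {
    recs <- vector("list", nVessels)
    covs <- vector("list", nVessels)
    if (nVessels > 0) {
      labels <- sample(PATTERN_LEVELS, nVessels, replace = TRUE,
                       prob = classProbs)
      for (i in seq_len(nVessels)) {
        params <- .randomPatternParams(labels[i])
        params@noiseSd <- noiseSd
        vid <- sprintf("V%03d", i)
        pid <- sprintf("P%03d", i)
        recs[[i]] <- .buildVessel(params, vid, pid)
        ci <- .drawCovariates(labels[i])
        covs[[i]] <- cbind(data.frame(vessel_id = vid, patient_id = pid,
                                      stringsAsFactors = FALSE),
                           ci,
                           data.frame(reference_diameter = params@proximalDiameter,
                                      label = labels[i],
                                      stringsAsFactors = FALSE))
      }
    }
    covdf <- if (nVessels > 0) do.call(rbind, covs) else
      data.frame(vessel_id = character(), patient_id = character(),
                 age = numeric(), sex = character(), smoking = character(),
                 hypertension = logical(), diabetes = logical(),
                 dyslipidaemia = logical(), reference_diameter = numeric(),
                 label = character(), stringsAsFactors = FALSE)
    new("VesselCohort", records = recs, covariates = covdf)
  })
}

#' Consensus label from an eight-rater panel
#'
#' The adjudication rule of the expert panel: a pattern supported by at
#' least five of the eight votes becomes the label (round
#' \code{"first_full"} when unanimous, else \code{"first_partial"});
#' otherwise the vessel goes to a second assessment stage, emulated here as
#' convergence to the ground truth.
#'
#' @param votes character vector of exactly 8 pattern votes.
#' @param truth the generating pattern, used only for the second stage.
#' @return list with \code{label} and \code{round}.
#' @examples
#' consensusLabel(rep("focal", 8), truth = "focal")
#' @export
consensusLabel <- function(votes, truth) {
  if (length(votes) != 8L)
    .stopf("consensusLabel: exactly 8 votes required, got %d", length(votes))
  if (!all(votes %in% PATTERN_LEVELS))
    .stopf("consensusLabel: votes must be pattern names")
  tab <- table(votes)
  top <- names(tab)[which.max(tab)]
  if (max(tab) >= 5L) {
    list(label = top,
         round = if (max(tab) == 8L) "first_full" else "first_partial")
  } else {
    list(label = truth, round = "second")
  }
}

#' Simulate one panel of eight rater votes
#'
#' Each rater reports the truth with probability \code{1 - errorRate};
#' otherwise a confusable class, with the mixed pattern acting as the
#' confusion hub (focal/diffuse/serial errors go to mixed with probability
#' 0.8, to the remaining classes with 0.1 each; errors on a mixed truth
#' spread uniformly over the other three patterns).
#'
#' @param truth the true pattern.
#' @param errorRate per-rater error probability (default 0.1).
#' @param nRaters panel size (default 8).
#' @return character vector of votes (uses the current RNG stream).
#' @export
simulateVotes <- function(truth, errorRate = 0.1, nRaters = 8L) {
  stopifnot(truth %in% PATTERN_LEVELS)
  others <- setdiff(PATTERN_LEVELS, truth)
  prob <- if (truth == "mixed") rep(1 / 3, 3) else
    ifelse(others == "mixed", 0.8, 0.1)
  vapply(seq_len(nRaters), function(i) {
    if (stats::runif(1) < errorRate) sample(others, 1, prob = prob) else truth
  }, character(1))
}
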