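#' Resample a raw pullback trace onto a uniform grid
#'
#' Linearly interpolates raw (position, value) samples onto a uniform grid
#' starting at the first raw position with the requested spacing (default
#' 0.35 mm, the sampling step of the virtual pullback). The grid has
#' \code{floor(L / spacing) + 1} points, so a trailing remainder shorter
#' than one spacing is dropped; when the vessel length is a multiple of the
#' spacing the grid ends exactly at the last raw position.
#'
#' @param rawPositions strictly increasing positions (mm), length >= 2.
#' @param rawValues muFR values at those positions.
#' @param spacing grid spacing in mm (default 0.35).
#' @param rawMld,rawRvd optional diameter samples at the same positions.
#' @return a \linkS4class{PullbackCurve}.
#' @examples
#' crv <- resampleCurve(c(0, 10), c(1.0, 0.8))
#' length(positions(crv))  # 29
#' @export
resampleCurve <- function(rawPositions, rawValues, spacing = 0.35,
                          rawMld = NULL, rawRvd = NULL) {
  if (length(rawPositions) < 2L || length(rawValues) < 2L)
    .stopf("resampleCurve: need at least 2 points")
  if (length(rawPositions) != length(rawValues))
    .stopf("resampleCurve: positions and values lengths differ")
  if (any(diff(rawPositions) <= 0))
    .stopf("resampleCurve: positions must be strictly increasing")
  if (spacing <= 0) .stopf("resampleCurve: spacing must be > 0")
  L <- rawPositions[length(rawPositions)] - rawPositions[1L]
  n <- floor(L / spacing + 1e-9) + 1L
  grid <- rawPositions[1L] + (seq_len(n) - 1L) * spacing
  interp <- function(y) {
    if (is.null(y)) return(numeric())
    stats::approx(rawPositions, y, xout = grid, rule = 2)$y
  }
  PullbackCurve(grid, interp(rawValues),
                mld = interp(rawMld), rvd = interp(rawRvd))
}

#' Non-increasing projection of a pullback trace
#'
#' Pressure ratios along a pullback can only fall (up to trace noise), so
#' all drop and gradient computations run on the least-squares
#' non-increasing projection of the muFR values (pool adjacent violators).
#' The operation is idempotent and leaves diameter curves untouched.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @return a \linkS4class{PullbackCurve} with non-increasing muFR.
#' @examples
#' crv <- PullbackCurve(c(0, 0.35, 0.7), c(1.0, 0.8, 0.9))
#' mufrValues(monotonize(crv))  # 1.00 0.85 0.85
#' @export
monotonize <- function(curve) {
  stopifnot(is(curve, "PullbackCurve"))
  y <- curve@mufr
  if (!is.unsorted(rev(y))) return(curve)   # already non-increasing
  fit <- stats::isoreg(curve@positions, -y)  # PAVA, equal weights
  PullbackCurve(curve@positions, pmin(pmax(-fit$yf, 0), 1),
                mld = curve@mld, rvd = curve@rvd)
}

#' Vessel-level muFR drop
#'
#' Proximal-minus-distal muFR difference on the monotonized curve. Virtual
#' pullbacks start at the normalized proximal value, so the endpoint
#' difference (not max minus min) is the vessel drop.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @return non-negative drop (may be 0 for a flat trace).
#' @export
deltaMufrVessel <- function(curve) {
  y <- monotonize(curve)@mufr
  y[1L] - y[length(y)]
}

#' Maximum muFR drop over a sliding window
#'
#' Largest drop of the monotonized trace over any along-vessel window of
#' the given length (default 20 mm). The window is discretized to
#' \code{floor(window / spacing)} grid steps; vessels shorter than the
#' window return the whole-vessel drop.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @param windowMm window length in mm (default 20).
#' @return the maximum windowed drop (unitless).
#' @export
maxDrop20mm <- function(curve, windowMm = 20) {
  y <- monotonize(curve)@mufr
  h <- gridSpacing(curve)
  n <- length(y)
  k <- floor(windowMm / h + 1e-9)
  if (k >= n - 1L) return(y[1L] - y[n])      # vessel shorter than window
  k <- max(1L, k)
  max(y[seq_len(n - k)] - y[seq_len(n - k) + k])
}

#' Length of vessel with functional disease
#'
#' Total length of grid segments whose local drop per mm on the
#' monotonized trace is at least \code{threshold}. The default threshold
#' (0.001/mm) is a noise floor an order of magnitude below the 0.025/mm
#' major-gradient cut-off: a segment losing less than 0.001 muFR per mm is
#' treated as functionally healthy.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @param threshold per-mm gradient above which a segment counts as
#'   diseased (default 0.001).
#' @return diseased length in mm.
#' @export
functionalDiseaseLength <- function(curve, threshold = 0.001) {
  y <- monotonize(curve)@mufr
  h <- gridSpacing(curve)
  g <- -diff(y) / h
  h * sum(g >= threshold - 1e-12)
}

#' Pullback pressure gradient index
#'
#' Computes the PPGi of a virtual pullback:
#' \deqn{PPGi = \frac{1}{2}\left(\frac{MaxPPG_{20mm}}{\Delta\mu FR_{vessel}}
#'   + \left(1 - \frac{L_{disease}}{L_{total}}\right)\right)}
#' Values near 1 indicate focal disease (the whole drop concentrated in a
#' short segment), values near 0 diffuse disease. The index is undefined on
#' a flat trace (zero vessel drop); such vessels should already have been
#' excluded as free of functional disease.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @param windowMm window for the maximum pressure drop (default 20 mm).
#' @param diseaseThreshold per-mm gradient defining functional disease
#'   (default 0.001; see \code{\link{functionalDiseaseLength}}).
#' @return a \linkS4class{PpgiComponents}.
#' @examples
#' s <- seq(0, 79.8, by = 0.35)
#' crv <- PullbackCurve(s, 1 - 0.3 / 79.8 * s)  # uniform decline
#' ppgiValue(computePpgi(crv))                  # ~0.125
#' @export
computePpgi <- function(curve, windowMm = 20, diseaseThreshold = 0.001) {
  delta <- deltaMufrVessel(curve)
  if (delta <= 0)
    .stopf("computePpgi: undefined index, vessel drop is zero (vessel should have been excluded)")
  maxDrop <- maxDrop20mm(curve, windowMm)
  dl <- functionalDiseaseLength(curve, diseaseThreshold)
  tl <- totalLength(curve)
  ppgi <- (maxDrop / delta + (1 - dl / tl)) / 2
  new("PpgiComponents", maxPpg20mm = maxDrop, deltaMufrVessel = delta,
      diseaseLengthMm = dl, totalLengthMm = tl, ppgi = ppgi)
}

#' Maximum local muFR gradient (d muFR / ds)
#'
#' The instantaneous along-vessel gradient, estimated as the maximum of
#' the negative first difference of the smoothed, monotonized trace
#' divided by the grid spacing. Smoothing is a centered moving average
#' spanning \code{smoothWindowMm} (default 2 mm) to keep the estimate
#' stable on 0.35-mm grids.
#'
#' @param curve a \linkS4class{PullbackCurve}.
#' @param smoothWindowMm smoothing window in mm (default 2).
#' @return the maximum gradient in 1/mm (>= 0).
#' @export
maxLocalGradient <- function(curve, smoothWindowMm = 2) {
  y <- monotonize(curve)@mufr
  h <- gridSpacing(curve)
  k <- 2L * floor(smoothWindowMm / (2 * h) + 1e-9) + 1L
  ys <- .movingAverage(y, k)
  max(c(0, -diff(ys) / h))
}

#' Major-gradient flag
#'
#' A local gradient of at least 0.025/mm marks the presence of a major
#' gradient (a locally severe lesion); below the cut-off it is absent.
#'
#' @param gradient gradient value(s) in 1/mm, >= 0.
#' @param cutoff per-mm cut-off (default 0.025).
#' @return logical vector.
#' @export
hasMajorGradient <- function(gradient, cutoff = 0.025) {
  stopifnot(all(gradient >= 0))
  gradient >= cutoff
}

#' Dichotomize disease pattern by the PPGi cut-off
#'
#' Classifies a PPGi value as focal (PPGi >= 0.78) or diffuse
#' (PPGi < 0.78), the validated dichotomization cut-off.
#'
#' @param ppgi PPGi value(s) in [0, 1].
#' @param cutoff cut-off (default 0.78).
#' @return character vector, "focal" or "diffuse".
#' @export
classifyByPpgiCutoff <- function(ppgi, cutoff = 0.78) {
  stopifnot(all(ppgi >= 0 & ppgi <= 1))
  ifelse(ppgi >= cutoff, "focal", "diffuse")
}

#' Hemodynamic significance and exclusion flags for a vessel
#'
#' A vessel is hemodynamically significant when its distal muFR is at most
#' 0.80 (the standard significance cut-off); a vessel with distal muFR
#' above 0.95 is considered without functional disease and must be dropped
#' from all pattern analyses.
#'
#' @param record a \linkS4class{VesselRecord}.
#' @return list with logical elements \code{significant} and
#'   \code{noFunctionalDisease}.
#' @export
vesselFlags <- function(record) {
  stopifnot(is(record, "VesselRecord"))
  list(significant = record@distalMufr <= 0.80,
       noFunctionalDisease = record@distalMufr > 0.95)
}
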