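#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even. Clinical percentages are
#' conventionally rounded half away from zero (84/160 = 52.5\% prints as
#' 53\%), so all percentage formatting and split-size arithmetic in this
#' package goes through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(52.5)   # 53
#' roundHalfUp(-2.5)   # -3
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a whole percentage
#'
#' @param x proportion(s) in [0, 1] (NA allowed).
#' @return character vector like \code{"53\%"}; \code{NA} stays \code{NA}.
#' @export
formatPercent <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- paste0(roundHalfUp(100 * x[ok]), "%")
  out
}

# Centered moving average with shrinking symmetric windows at the edges.
# k must be odd; a line is reproduced exactly in the interior and at the
# edges (symmetric windows preserve linear trends).
.movingAverage <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n < 3L) return(x)
  h <- (k - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
  }
  out
}

# Truncated normal draws by inverse-CDF (exact, vectorized), using the
# current RNG stream.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, lo, hi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

# Evaluate a block with a locally seeded RNG, restoring the caller's
# .Random.seed afterwards so seeded helpers do not clobber the session.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
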