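# Fixture builders and independent oracles used across test files.

# A uniform-grid curve from explicit values.
makeCurve <- function(values, spacing = 0.35, ...) {
  PullbackCurve((seq_along(values) - 1L) * spacing, values, ...)
}

# A linear decline over lengthMm with the given slope (per mm).
linearCurve <- function(lengthMm = 79.8, slope = 0.00375, spacing = 0.35) {
  s <- seq(0, lengthMm, by = spacing)
  PullbackCurve(s, 1 - slope * s)
}

# A single linear ramp of depth `drop` between from and to (mm), flat
# elsewhere; endpoints chosen on-grid by the caller.
stepCurve <- function(lengthMm = 79.8, drop = 0.3, from = 36.75, to = 43.75,
                      spacing = 0.35) {
  s <- seq(0, lengthMm, by = spacing)
  PullbackCurve(s, 1 - drop * pmin(pmax((s - from) / (to - from), 0), 1))
}

# Random non-increasing curve: cumulative sum of non-negative increments,
# occasionally sparse so flat stretches occur.
randomMonotoneCurve <- function(lengthMm = runif(1, 40, 120),
                                spacing = 0.35) {
  s <- seq(0, lengthMm, by = spacing)
  inc <- rexp(length(s) - 1L, 50) * rbinom(length(s) - 1L, 1, 0.3)
  drop <- c(0, cumsum(inc))
  if (max(drop) > 0.9) drop <- drop * 0.9 / max(drop)
  PullbackCurve(s, 1 - drop)
}

# Independent sliding-window oracle: for every start index find the last
# grid point within windowMm and take the value difference; maximum over
# starts. Works directly on a non-increasing value vector.
bruteMaxDrop <- function(positions, values, windowMm = 20) {
  n <- length(values)
  if (positions[n] - positions[1L] < windowMm) return(values[1L] - values[n])
  best <- 0
  for (i in seq_len(n)) {
    j <- max(which(positions <= positions[i] + windowMm + 1e-9))
    if (j > i) best <- max(best, values[i] - values[j])
  }
  best
}

# Unpenalized logistic MLE by Newton/IRLS (independent of glmnet).
irlsLogistic <- function(X, y, maxit = 100, tol = 1e-12) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    H <- crossprod(X1 * w, X1)
    g <- crossprod(X1, y - p)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# Small labelled cohort for pipeline tests.
smallCohort <- function(n = 80, seed = 42) simulateCohort(n, seed = seed)
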