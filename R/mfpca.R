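## Multivariate functional PCA of the (muFR, diameter) curve pair.
##
## The estimator is the standard two-stage construction: univariate
## Karhunen-Loeve expansions per variable (quadrature-weighted
## eigendecomposition of the sample covariance surface), then an
## eigendecomposition of the covariance of the stacked univariate scores.
## The eigenvectors of that score covariance form the combination matrix;
## multivariate eigenfunctions are the univariate eigenfunctions combined
## by it, and they are orthonormal under the summed per-variable
## quadrature inner product by construction.

.quadWeights <- function(grid, type = c("trapezoid", "uniform")) {
  type <- match.arg(type)
  G <- length(grid)
  if (type == "uniform") return(rep(1, G))
  h <- diff(grid)
  w <- numeric(G)
  w[1L] <- h[1L] / 2
  w[G] <- h[G - 1L] / 2
  if (G > 2L) w[2:(G - 1L)] <- (h[-1L] + h[-(G - 1L)]) / 2
  w
}

#' Register vessel curves onto a common normalized grid
#'
#' Each vessel's domain is linearly rescaled to [0, 1] and its curves are
#' interpolated onto a common grid, yielding the registered functional
#' sample used by MFPCA. (PPGi is length-sensitive and is computed on the
#' physical grid; shape analysis need not be, so normalized-domain
#' registration is the default.)
#'
#' @param x a \linkS4class{VesselCohort} or list of
#'   \linkS4class{VesselRecord}.
#' @param nGrid number of grid points (default 101).
#' @param variables curve variables to register, subset of
#'   \code{c("mufr", "mld", "rvd")} (default muFR and minimal lumen
#'   diameter).
#' @param onMissing what to do with vessels lacking a requested diameter
#'   curve: \code{"fail"} (default) or \code{"drop"}.
#' @return a \linkS4class{FunctionalSample}.
#' @export
registerCurves <- function(x, nGrid = 101, variables = c("mufr", "mld"),
                           onMissing = c("fail", "drop")) {
  onMissing <- match.arg(onMissing)
  if (is(x, "VesselCohort")) x <- vesselRecords(x)
  stopifnot(all(vapply(x, is, logical(1), "VesselRecord")))
  variables <- match.arg(variables, c("mufr", "mld", "rvd"),
                         several.ok = TRUE)
  has <- vapply(x, function(r) {
    crv <- r@curve
    all(vapply(variables, function(v) length(slot(crv, v)) > 0, logical(1)))
  }, logical(1))
  if (!all(has)) {
    if (onMissing == "fail")
      .stopf("registerCurves: %d vessel(s) lack a requested curve variable",
             sum(!has))
    x <- x[has]
  }
  if (!length(x)) .stopf("registerCurves: no vessels to register")
  grid <- seq(0, 1, length.out = nGrid)
  vals <- lapply(variables, function(v) {
    m <- t(vapply(x, function(r) {
      crv <- r@curve
      p <- crv@positions
      u <- (p - p[1L]) / (p[length(p)] - p[1L])
      stats::approx(u, slot(crv, v), xout = grid, rule = 2)$y
    }, numeric(nGrid)))
    rownames(m) <- NULL
    m
  })
  names(vals) <- variables
  new("FunctionalSample", grid = grid, values = vals,
      vesselIds = vapply(x, function(r) r@vesselId, character(1)))
}

#' Univariate functional PCA by quadrature eigendecomposition
#'
#' Centers the curves by the pointwise mean, eigendecomposes the
#' quadrature-weighted sample covariance operator, and retains the
#' smallest number of components whose cumulative eigenvalue fraction
#' reaches \code{pve}. Eigenfunctions have unit norm under the weighted
#' inner product; signs are fixed so each eigenfunction's weighted
#' integral is non-negative (ties broken toward a positive first nonzero
#' loading).
#'
#' @param values subjects x G matrix.
#' @param grid abscissa of the G columns.
#' @param pve proportion of variance explained to retain (default 0.99).
#' @param weights quadrature rule, \code{"trapezoid"} (default) or
#'   \code{"uniform"} (unit weights; with a uniform grid this makes scores
#'   identical to matrix PCA scores).
#' @return list with \code{mean}, \code{eigenfunctions} (G x m),
#'   \code{eigenvalues} (length m), \code{scores} (subjects x m),
#'   \code{weights}, \code{grid}, and \code{totalVariance} (the integrated
#'   pointwise variance).
#' @export
fitUnivariateFpca <- function(values, grid, pve = 0.99,
                              weights = c("trapezoid", "uniform")) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2L) .stopf("fitUnivariateFpca: need at least 2 subjects")
  if (ncol(values) != length(grid))
    .stopf("fitUnivariateFpca: grid length must match columns")
  w <- .quadWeights(grid, match.arg(weights))
  mu <- colMeans(values)
  Xc <- sweep(values, 2L, mu)
  sw <- sqrt(w)
  Y <- sweep(Xc, 2L, sw, `*`)
  C <- crossprod(Y) / (n - 1L)           # weighted covariance, G x G
  eg <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total <- sum(lambda)                   # = integrated pointwise variance
  m <- if (total <= 0) 1L else
    which(cumsum(lambda) / total >= pve - 1e-12)[1L]
  lambda <- lambda[seq_len(m)]
  phi <- sweep(eg$vectors[, seq_len(m), drop = FALSE], 1L, sw, `/`)
  # sign convention
  for (j in seq_len(m)) {
    s <- sum(phi[, j] * w)
    if (abs(s) < 1e-10) {
      nz <- which(abs(phi[, j]) > 1e-10)[1L]
      s <- if (length(nz) && !is.na(nz)) phi[nz, j] else 1
    }
    if (s < 0) phi[, j] <- -phi[, j]
  }
  scores <- Xc %*% (phi * w)
  list(mean = mu, eigenfunctions = phi, eigenvalues = lambda,
       scores = scores, weights = w, grid = grid, totalVariance = total)
}

#' Fit multivariate functional PCA
#'
#' Fits univariate FPCA per variable, stacks the univariate score
#' vectors, and eigendecomposes their covariance. The resulting
#' eigenvectors (the combination matrix) map stacked univariate scores to
#' multivariate scores; multivariate eigenfunctions are the univariate
#' eigenfunctions combined blockwise by the same matrix.
#'
#' @param sample a \linkS4class{FunctionalSample}.
#' @param nComponents multivariate components to retain (default 3, the
#'   number of score features fed to the classifiers).
#' @param pve univariate truncation level (default 0.99).
#' @param weights quadrature rule (see \code{\link{fitUnivariateFpca}}).
#' @return an \linkS4class{MFPCAModel}.
#' @export
fitMfpca <- function(sample, nComponents = 3, pve = 0.99,
                     weights = c("trapezoid", "uniform")) {
  stopifnot(is(sample, "FunctionalSample"))
  weights <- match.arg(weights)
  vars <- names(sample@values)
  fits <- lapply(vars, function(v)
    fitUnivariateFpca(sample@values[[v]], sample@grid, pve = pve,
                      weights = weights))
  names(fits) <- vars
  Z <- do.call(cbind, lapply(fits, `[[`, "scores"))
  M <- ncol(Z)
  if (nComponents > M) {
    warning(sprintf(
      "fitMfpca: %d components requested but only %d univariate scores available; truncating",
      nComponents, M))
    nComponents <- M
  }
  Czz <- stats::cov(Z)
  eg <- eigen(Czz, symmetric = TRUE)
  K <- as.integer(nComponents)
  Cmat <- eg$vectors[, seq_len(K), drop = FALSE]
  nu <- pmax(eg$values[seq_len(K)], 0)
  # sign convention on the multivariate eigenfunctions: non-negative
  # summed weighted integral across variables
  blocks <- vapply(fits, function(f) ncol(f$eigenfunctions), integer(1))
  offs <- c(0L, cumsum(blocks))
  w <- fits[[1L]]$weights
  for (k in seq_len(K)) {
    s <- 0
    for (j in seq_along(vars)) {
      cb <- Cmat[(offs[j] + 1L):offs[j + 1L], k]
      s <- s + sum((fits[[j]]$eigenfunctions %*% cb) * w)
    }
    if (abs(s) < 1e-10) {
      nz <- which(abs(Cmat[, k]) > 1e-10)[1L]
      if (!is.na(nz)) s <- Cmat[nz, k]
    }
    if (s < 0) Cmat[, k] <- -Cmat[, k]
  }
  new("MFPCAModel", grid = sample@grid, weights = w,
      variables = vars,
      meanFunctions = lapply(fits, `[[`, "mean"),
      uniEigenfunctions = lapply(fits, `[[`, "eigenfunctions"),
      uniEigenvalues = lapply(fits, `[[`, "eigenvalues"),
      combinationMatrix = Cmat, multiEigenvalues = nu,
      nComponents = K)
}

.checkGrid <- function(model, sample) {
  if (length(model@grid) != length(sample@grid) ||
      max(abs(model@grid - sample@grid)) > 1e-8)
    .stopf("sample grid does not match the model grid")
  miss <- setdiff(model@variables, names(sample@values))
  if (length(miss))
    .stopf("sample lacks model variable(s): %s", paste(miss, collapse = ", "))
}

#' Project curves onto a fitted MFPCA model
#'
#' Centers the sample with the model's mean functions and projects onto
#' the multivariate eigenfunctions via the quadrature inner product. On
#' the training sample the score columns are uncorrelated with variances
#' equal to the multivariate eigenvalues.
#'
#' @param model an \linkS4class{MFPCAModel}.
#' @param sample a \linkS4class{FunctionalSample} registered on the
#'   model's grid.
#' @return subjects x nComponents score matrix.
#' @export
mfpcaScores <- function(model, sample) {
  stopifnot(is(model, "MFPCAModel"), is(sample, "FunctionalSample"))
  .checkGrid(model, sample)
  w <- model@weights
  Zs <- lapply(model@variables, function(v) {
    Xc <- sweep(sample@values[[v]], 2L, model@meanFunctions[[v]])
    Xc %*% (model@uniEigenfunctions[[v]] * w)
  })
  do.call(cbind, Zs) %*% model@combinationMatrix
}

#' Reconstruct curves from multivariate scores
#'
#' @param model an \linkS4class{MFPCAModel}.
#' @param scores subjects x nComponents matrix (as returned by
#'   \code{\link{mfpcaScores}}).
#' @return named list of subjects x G matrices, one per model variable.
#' @export
reconstructCurves <- function(model, scores) {
  stopifnot(is(model, "MFPCAModel"))
  scores <- as.matrix(scores)
  blocks <- vapply(model@uniEigenfunctions, ncol, integer(1))
  offs <- c(0L, cumsum(blocks))
  out <- lapply(seq_along(model@variables), function(j) {
    cb <- model@combinationMatrix[(offs[j] + 1L):offs[j + 1L], , drop = FALSE]
    psi <- model@uniEigenfunctions[[j]] %*% cb      # G x K
    sweep(scores %*% t(psi), 2L, model@meanFunctions[[j]], `+`)
  })
  names(out) <- model@variables
  out
}
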