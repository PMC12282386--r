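# Multivariate functional PCA: registration, univariate eigenanalysis,
# score combination, projection and reconstruction.

# registered single-variable sample from a values matrix
asSample <- function(X, grid = seq(0, 1, length.out = ncol(X)),
                     name = "mufr") {
  new("FunctionalSample", grid = grid,
      values = setNames(list(X), name),
      vesselIds = sprintf("V%03d", seq_len(nrow(X))))
}

test_that("registerCurves rescales every vessel onto the common grid", {
  mk <- function(L, slope) {
    s <- seq(0, L, by = 0.35)
    VesselRecord("v", "p", PullbackCurve(s, 1 - slope * s,
                                         mld = rep(2, length(s)),
                                         rvd = rep(3, length(s))), 3.5)
  }
  sm <- registerCurves(list(mk(40, 0.002), mk(120, 0.001)), nGrid = 101)
  expect_equal(sm@grid, seq(0, 1, length.out = 101))
  expect_equal(dim(sm@values$mufr), c(2L, 101L))
  # linear curves stay closed-form linear after registration
  L1 <- 0.35 * floor(40 / 0.35)   # actual sampled span
  expect_equal(sm@values$mufr[1, ], 1 - 0.002 * L1 * sm@grid, tolerance = 1e-9)

  # missing diameter curves: fail by default, droppable on request
  noMld <- VesselRecord("x", "p", makeCurve(seq(1, 0.8, length.out = 30)), 3)
  expect_error(registerCurves(list(mk(40, 0.002), noMld)), "lack")
  sm2 <- registerCurves(list(mk(40, 0.002), noMld), onMissing = "drop")
  expect_identical(sm2@vesselIds, "v")
})

test_that("univariate FPCA recovers a rank-one construction", {
  grid <- seq(0, 1, length.out = 101)
  w <- PullbackPatterns:::.quadWeights(grid)
  phi <- sin(pi * grid)
  phi <- phi / sqrt(sum(phi^2 * w))          # unit norm under quadrature
  mu <- 1 - 0.3 * grid
  set.seed(5)
  a <- rnorm(40, sd = 0.2)
  X <- outer(rep(1, 40), mu) + outer(a, phi)
  f <- fitUnivariateFpca(X, grid)
  expect_equal(f$eigenvalues[1L], var(a), tolerance = 1e-8)
  s1 <- f$scores[, 1L]
  if (cor(s1, a) < 0) s1 <- -s1
  expect_equal(s1, a - mean(a), tolerance = 1e-8)
  expect_equal(f$mean, colMeans(X))

  # trace identity: total variance equals integrated pointwise variance
  set.seed(6)
  Y <- matrix(rnorm(40 * 101), 40)
  g <- fitUnivariateFpca(Y, grid, pve = 1)
  expect_equal(g$totalVariance, sum(apply(Y, 2, var) * w), tolerance = 1e-8)
  expect_equal(sum(g$eigenvalues), g$totalVariance, tolerance = 1e-8)

  # identical curves: no variance anywhere
  Z <- outer(rep(1, 10), mu)
  expect_equal(fitUnivariateFpca(Z, grid)$eigenvalues, 0)
  expect_error(fitUnivariateFpca(Z[1, , drop = FALSE], grid), "2 subjects")
})

test_that("single-variable MFPCA with uniform weights equals matrix PCA", {
  set.seed(8)
  X <- matrix(rnorm(200 * 60), 200) %*% diag(exp(-seq(0, 3, length.out = 60)))
  sm <- asSample(X, grid = seq(0, 1, length.out = 60))
  model <- fitMfpca(sm, nComponents = 3, weights = "uniform")
  sc <- mfpcaScores(model, sm)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    ref <- pc$x[, k]
    got <- sc[, k]
    if (sum(ref * got) < 0) got <- -got
    expect_equal(got, unname(ref), tolerance = 1e-6)
    expect_equal(model@multiEigenvalues[k], unname(pc$sdev[k]^2),
                 tolerance = 1e-6)
  }
})

test_that("duplicating a variable doubles the leading eigenvalue", {
  set.seed(9)
  grid <- seq(0, 1, length.out = 51)
  X <- outer(rnorm(60), sin(pi * grid)) + outer(rnorm(60, sd = 0.3),
                                                cos(2 * pi * grid))
  one <- fitMfpca(asSample(X, grid), nComponents = 2)
  two <- fitMfpca(new("FunctionalSample", grid = grid,
                      values = list(a = X, b = X),
                      vesselIds = sprintf("V%d", 1:60)), nComponents = 2)
  expect_equal(two@multiEigenvalues[1L], 2 * one@multiEigenvalues[1L],
               tolerance = 1e-8)
  # the leading combination vector loads both variable blocks equally
  m <- ncol(one@uniEigenfunctions[[1L]])
  cb <- two@combinationMatrix[, 1L]
  expect_equal(cb[seq_len(m)], cb[m + seq_len(m)], tolerance = 1e-8)
})

test_that("multivariate eigenfunctions are orthonormal under the summed inner product", {
  coh <- smallCohort(40)
  sm <- registerCurves(coh)
  model <- fitMfpca(sm, nComponents = 3)
  w <- model@weights
  blocks <- vapply(model@uniEigenfunctions, ncol, integer(1))
  offs <- c(0L, cumsum(blocks))
  G <- length(model@grid)
  K <- model@nComponents
  gram <- matrix(0, K, K)
  for (j in seq_along(model@variables)) {
    cb <- model@combinationMatrix[(offs[j] + 1L):offs[j + 1L], , drop = FALSE]
    psi <- model@uniEigenfunctions[[j]] %*% cb
    gram <- gram + t(psi) %*% (psi * w)
  }
  expect_equal(gram, diag(K), tolerance = 1e-8)
  expect_true(all(diff(model@multiEigenvalues) <= 1e-10))
  expect_true(all(model@multiEigenvalues >= 0))
})

test_that("training scores have eigenvalue variances; mean curve scores zero", {
  coh <- smallCohort(50)
  sm <- registerCurves(coh)
  model <- fitMfpca(sm, nComponents = 3)
  sc <- mfpcaScores(model, sm)
  expect_equal(unname(apply(sc, 2, var)), model@multiEigenvalues,
               tolerance = 1e-6)
  expect_lt(max(abs(cov(sc)[lower.tri(cov(sc))])), 1e-8)
  # the mean curve projects to the zero score vector
  meanSample <- new("FunctionalSample", grid = sm@grid,
                    values = lapply(model@meanFunctions, function(m)
                      matrix(m, nrow = 1)),
                    vesselIds = "mean")
  expect_equal(max(abs(mfpcaScores(model, meanSample))), 0, tolerance = 1e-10)
})

test_that("reconstruction error is bounded and monotone in components", {
  coh <- smallCohort(50)
  sm <- registerCurves(coh, variables = "mufr")
  full <- fitUnivariateFpca(sm@values$mufr, sm@grid, pve = 1)
  total <- full$totalVariance
  w <- full$weights
  ise <- function(K) {
    model <- suppressWarnings(fitMfpca(sm, nComponents = K, pve = 0.99))
    rec <- reconstructCurves(model, mfpcaScores(model, sm))$mufr
    mean(rowSums((rec - sm@values$mufr)^2 * rep(w, each = nrow(rec))))
  }
  errs <- vapply(1:4, ise, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  # truncation bound for the pve-limited expansion
  m99 <- suppressWarnings(fitMfpca(sm, nComponents = 50, pve = 0.99))
  rec <- reconstructCurves(m99, mfpcaScores(m99, sm))$mufr
  err <- mean(rowSums((rec - sm@values$mufr)^2 * rep(w, each = nrow(rec))))
  expect_lte(err, 0.01 * total + 1e-10)
})

test_that("scores respect permutation and constant-shift invariances", {
  coh <- smallCohort(30)
  sm <- registerCurves(coh)
  model <- fitMfpca(sm, nComponents = 3)
  sc <- mfpcaScores(model, sm)
  perm <- sample(seq_len(30))
  smP <- PullbackPatterns:::.sampleRows(sm, perm)
  expect_equal(mfpcaScores(model, smP), sc[perm, ], tolerance = 1e-12)
  # adding a constant to every curve only shifts the mean
  smC <- new("FunctionalSample", grid = sm@grid,
             values = lapply(sm@values, function(m) m + 0.37),
             vesselIds = sm@vesselIds)
  modelC <- fitMfpca(smC, nComponents = 3)
  scC <- mfpcaScores(modelC, smC)
  for (k in 1:3) {
    s <- if (sum(scC[, k] * sc[, k]) < 0) -1 else 1
    expect_equal(s * scC[, k], sc[, k], tolerance = 1e-8)
  }
})

test_that("requesting more components than scores truncates with a warning", {
  grid <- seq(0, 1, length.out = 21)
  X <- outer(rnorm(12), sin(pi * grid))      # rank one
  expect_warning(m <- fitMfpca(asSample(X, grid), nComponents = 5),
                 "truncating")
  expect_lte(m@nComponents, 5L)
})

test_that("MFPCA models survive a JSON round-trip", {
  coh <- smallCohort(25)
  sm <- registerCurves(coh)
  model <- fitMfpca(sm, nComponents = 3)
  path <- tempfile(fileext = ".json")
  writeMfpcaJson(model, path)
  back <- readMfpcaJson(path)
  expect_equal(mfpcaScores(back, sm), mfpcaScores(model, sm),
               tolerance = 1e-12)
  expect_equal(back@multiEigenvalues, model@multiEigenvalues)
  unlink(path)
})
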