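# Confusion metrics, ROC/AUC, splitting and the repeated-split harness.

test_that("confusionMetrics handles identities and empty denominators", {
  set.seed(51)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 30) + 1, 2,
                dimnames = list(c("neg", "pos"), c("neg", "pos")))
    cm <- confusionMatrix(m)
    met <- confusionMetrics(cm, "pos")
    P <- sum(m["pos", ]); N <- sum(m["neg", ])
    expect_equal(met$accuracy,
                 (met$sensitivity * P + met$specificity * N) / (P + N))
  }
  # zero denominators are NA, never 0
  cm0 <- confusionMatrix(matrix(c(5, 0, 3, 0), 2,
                                dimnames = list(c("neg", "pos"),
                                                c("neg", "pos"))))
  expect_true(is.na(confusionMetrics(cm0, "pos")$sensitivity))  # empty truth row
  cm1 <- confusionMatrix(matrix(c(5, 2, 0, 0), 2,
                                dimnames = list(c("neg", "pos"),
                                                c("neg", "pos"))))
  expect_true(is.na(confusionMetrics(cm1, "pos")$ppv))  # nothing called positive
  expect_error(confusionMetrics(confusionMatrix(diag(3)), "1"), "2x2")
  # all-correct diagonal
  metD <- confusionMetrics(confusionMatrix(diag(c(10, 20)),
                                           c("neg", "pos")), "pos")
  expect_equal(unlist(metD), c(accuracy = 1, sensitivity = 1,
                               specificity = 1, ppv = 1, npv = 1))
})

test_that("rocAuc equals the brute-force pairwise probability", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  set.seed(53)
  for (rep in 1:10) {
    sc <- round(runif(50), 2)     # rounding forces ties
    lb <- runif(50) < 0.4
    if (!any(lb) || all(lb)) next
    pairs <- expand.grid(p = which(lb), n = which(!lb))
    brute <- mean(ifelse(sc[pairs$p] > sc[pairs$n], 1,
                         ifelse(sc[pairs$p] == sc[pairs$n], 0.5, 0)))
    expect_equal(rocAuc(sc, lb), brute, tolerance = 1e-12)
  }
  # independent scores concentrate near 1/2
  set.seed(55)
  auc <- rocAuc(rnorm(2000), runif(2000) < 0.5)
  expect_lt(abs(auc - 0.5), 0.03)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("rocAuc matches pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(57)
  sc <- rnorm(80)
  lb <- runif(80) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(sc, lb), ref, tolerance = 1e-12)
})

test_that("one-vs-rest AUC reduces to per-class binary AUCs", {
  P <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  colnames(P) <- c("a", "b", "c")
  lab <- c("a", "b", "c", "a", "b", "c")
  expect_equal(unname(oneVsRestAuc(P, lab)), c(1, 1, 1))
  U <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(oneVsRestAuc(U, lab)), c(0.5, 0.5, 0.5))
  # identical score columns give identical AUCs by symmetry
  set.seed(59)
  Q <- cbind(a = runif(30), b = runif(30))
  Q <- cbind(Q, c = Q[, "b"])
  lab2 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  lab2[1:3] <- c("a", "b", "c")
  auc <- oneVsRestAuc(Q / rowSums(Q) * 0 + Q, lab2)  # raw scores suffice
  expect_equal(auc[["b"]], rocAuc(Q[, "b"], lab2 == "b"))
  expect_error(oneVsRestAuc(U, rep("a", 6)), "absent")
})

test_that("rocCurve traces the empirical ROC whose trapezoid area is the AUC", {
  set.seed(61)
  sc <- round(rnorm(60), 1)
  lb <- runif(60) < 0.5
  rc <- rocCurve(sc, lb)
  expect_equal(rc$fpr[1L], 0); expect_equal(rc$tpr[1L], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, rocAuc(sc, lb), tolerance = 1e-12)
})

test_that("splitData reproduces the study's per-stratum split sizes", {
  sp <- splitData(rep(c("focal", "diffuse"), c(160, 74)), seed = 1)
  expect_length(sp$train, 176L)
  expect_length(sp$test, 58L)
  sp2 <- splitData(rep(c("focal", "diffuse", "mixed", "serial"),
                       c(160, 74, 82, 27)), seed = 1)
  expect_length(sp2$train, 258L)
  expect_length(sp2$test, 85L)
  # stratification keeps per-class proportions
  lab <- rep(c("focal", "diffuse"), c(160, 74))
  expect_equal(sum(lab[sp$train] == "focal"), 120L)
  expect_equal(sum(lab[sp$train] == "diffuse"), 56L)
  # determinism and disjointness
  expect_identical(sp, splitData(rep(c("focal", "diffuse"), c(160, 74)),
                                 seed = 1))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:234)
  expect_error(splitData(c("a", "b", "b"), stratify = TRUE), "fewer than 2")
})

prepSmall <- function(n = 90, seed = 42)
  prepareCohortData(simulateCohort(n, seed = seed))

test_that("repeatEvaluate at one iteration equals the single-split pipeline", {
  prep <- prepSmall()
  rep1 <- repeatEvaluate(prep, "focal_vs_diffuse", "penalized_logistic",
                         includePpgi = TRUE, nIterations = 1, baseSeed = 10)
  strat <- prep$labels[prep$labels %in% c("focal", "diffuse")]
  sp <- splitData(strat, seed = 11)           # iteration 1 uses baseSeed + 1
  single <- evaluateSplit(prep, "focal_vs_diffuse", "penalized_logistic",
                          sp$train, sp$test, includePpgi = TRUE, seed = 11)
  expect_equal(unlist(iterationMetrics(rep1)[1, ]),
               unlist(single$metrics))
})

test_that("a degenerate always-positive rule scores the prevalence exactly", {
  prep <- prepSmall()
  # cutoff 0 predicts focal for every vessel
  repc <- repeatEvaluate(prep, "focal_vs_diffuse", "ppgi_cutoff",
                         cutoff = 0, nIterations = 10, baseSeed = 3)
  strat <- prep$labels[prep$labels %in% c("focal", "diffuse")]
  nf <- sum(strat == "focal"); nd <- sum(strat == "diffuse")
  testFocal <- nf - roundHalfUp(0.75 * nf)
  testAll <- testFocal + nd - roundHalfUp(0.75 * nd)
  it <- iterationMetrics(repc)
  expect_true(all(abs(it$accuracy - testFocal / testAll) < 1e-12))
  expect_true(all(it$sensitivity == 1))
  # the cut-off rule yields no probability scores, hence no AUC
  expect_true(all(is.na(it$auc)))
  expect_true(is.na(summaryTable(repc)$mean[summaryTable(repc)$metric == "auc"]))
})

test_that("the three-class task reports per-class metrics and rejects the cutoff", {
  prep <- prepSmall(120)
  repm <- repeatEvaluate(prep, "three_class", "random_forest",
                         nIterations = 2, baseSeed = 5, nTrees = 150)
  it <- iterationMetrics(repm)
  expect_true(all(c("accuracy", "sensitivity_diffuse", "auc_others")
                  %in% names(it)))
  ok <- !is.na(unlist(it))
  expect_true(all(unlist(it)[ok] >= 0 & unlist(it)[ok] <= 1))
  expect_error(repeatEvaluate(prep, "three_class", "ppgi_cutoff",
                              nIterations = 1), "binary")
})

test_that("corrupting test labels changes neither the fit nor the predictions", {
  prep <- prepSmall()
  keep <- prep$labels %in% c("focal", "diffuse")
  y <- factor(prep$labels[keep], c("diffuse", "focal"))
  sp <- splitData(as.character(y), seed = 2)
  clean <- evaluateSplit(prep, "focal_vs_diffuse", "penalized_logistic",
                         sp$train, sp$test, seed = 2)
  corrupted <- as.character(y)
  corrupted[sp$test] <- sample(c("diffuse", "focal"), length(sp$test),
                               replace = TRUE)
  dirty <- evaluateSplit(prep, "focal_vs_diffuse", "penalized_logistic",
                         sp$train, sp$test, seed = 2,
                         labelsOverride = corrupted)
  expect_identical(dirty$predictions, clean$predictions)
  expect_identical(dirty$proba, clean$proba)
})

test_that("evaluation summaries bracket their means and reports serialize", {
  prep <- prepSmall()
  repc <- repeatEvaluate(prep, "focal_vs_diffuse", "ppgi_cutoff",
                         nIterations = 20, baseSeed = 7)
  s <- summaryTable(repc)
  ok <- !is.na(s$mean)
  expect_true(all(s$ci_lower[ok] <= s$mean[ok] + 1e-12))
  expect_true(all(s$mean[ok] <= s$ci_upper[ok] + 1e-12))
  path <- tempfile(fileext = ".json")
  writeReportJson(repc, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_iterations, 20L)
  expect_equal(back$metrics$accuracy$mean,
               s$mean[s$metric == "accuracy"], tolerance = 1e-12)
  unlink(path)
})

test_that("percentages print with half-away-from-zero rounding", {
  expect_identical(formatPercent(84 / 160), "53%")   # 52.5 -> 53
  expect_identical(formatPercent(72 / 74), "97%")
  expect_identical(roundHalfUp(0.5), 1)
  expect_identical(roundHalfUp(-0.5), -1)
  expect_identical(roundHalfUp(2.25, 1), 2.3)
  expect_identical(formatPercent(c(0.5, NA))[2], NA_character_)
})
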