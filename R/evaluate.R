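## Repeated-split evaluation harness.
##
## Tasks:
##   focal_vs_diffuse  - only focal and diffuse vessels (the 234-vessel
##                       scale problem); positive class focal.
##   focal_vs_nonfocal - all vessels, diffuse+mixed+serial pooled as
##                       "nonfocal"; positive class focal.
##   three_class       - all vessels, mixed+serial pooled as "others".
##
## Each iteration re-splits, refits MFPCA and the classifier on the
## training set only, and scores the held-out test set, so no information
## leaks from test to train. Splits are stratified by the full four-class
## pattern label with per-stratum train size roundHalfUp(0.75 * n).

.TASKS <- c("focal_vs_diffuse", "focal_vs_nonfocal", "three_class")
.METHODS <- c("ppgi_cutoff", "penalized_logistic", "random_forest")

#' Reproducible train/test split
#'
#' @param labels stratification labels, one per record.
#' @param trainFraction fraction assigned to training (default 0.75).
#' @param stratify stratified split (default TRUE); per-stratum train size
#'   is \code{roundHalfUp(trainFraction * n)}.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @examples
#' sp <- splitData(rep(c("focal", "diffuse"), c(160, 74)), seed = 1)
#' lengths(sp)  # 176 / 58
#' @export
splitData <- function(labels, trainFraction = 0.75, stratify = TRUE,
                      seed = 1) {
  n <- length(labels)
  if (n == 0L) .stopf("splitData: empty dataset")
  .withSeed(seed, {
    if (stratify) {
      train <- integer()
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 2L)
          .stopf("splitData: stratum '%s' has fewer than 2 members", cl)
        k <- roundHalfUp(trainFraction * length(idx))
        k <- min(max(k, 1L), length(idx) - 1L)  # keep both sides non-empty
        train <- c(train, sample(idx, k))
      }
    } else {
      k <- roundHalfUp(trainFraction * n)
      train <- sample.int(n, min(max(k, 1L), n - 1L))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

.taskLabels <- function(labels4, task) {
  switch(task,
    focal_vs_diffuse = factor(labels4, levels = c("diffuse", "focal")),
    focal_vs_nonfocal = factor(ifelse(labels4 == "focal", "focal", "nonfocal"),
                               levels = c("nonfocal", "focal")),
    three_class = factor(ifelse(labels4 %in% c("mixed", "serial"), "others",
                                labels4),
                         levels = c("diffuse", "focal", "others")),
    .stopf("unknown task '%s'", task))
}

#' Precompute the per-vessel quantities the evaluation loop reuses
#'
#' Registers the curves once and computes the physiological indices; the
#' MFPCA model itself is refitted inside every training split.
#'
#' @param cohort a labelled \linkS4class{VesselCohort}.
#' @param nGrid registration grid size (default 101).
#' @param dropNoDisease drop vessels with distal muFR > 0.95 (default
#'   TRUE, the exclusion rule for vessels without functional disease).
#' @return list with the registered \code{sample}, the \code{indices}
#'   table, the four-class \code{labels}, and the (possibly subset)
#'   \code{cohort}.
#' @export
prepareCohortData <- function(cohort, nGrid = 101, dropNoDisease = TRUE) {
  stopifnot(is(cohort, "VesselCohort"))
  labels4 <- cohort@covariates$label
  if (anyNA(labels4) || any(!labels4 %in% PATTERN_LEVELS))
    .stopf("prepareCohortData: every vessel needs a pattern label")
  indices <- cohortIndices(cohort)
  if (dropNoDisease && any(indices$no_functional_disease)) {
    keep <- !indices$no_functional_disease
    cohort <- new("VesselCohort", records = cohort@records[keep],
                  covariates = cohort@covariates[keep, , drop = FALSE])
    indices <- indices[keep, , drop = FALSE]
    labels4 <- labels4[keep]
  }
  sample <- registerCurves(cohort, nGrid = nGrid)
  list(cohort = cohort, sample = sample, indices = indices,
       labels = labels4)
}

# Subset a FunctionalSample by row index.
.sampleRows <- function(sample, idx) {
  new("FunctionalSample", grid = sample@grid,
      values = lapply(sample@values, function(m) m[idx, , drop = FALSE]),
      vesselIds = sample@vesselIds[idx])
}

#' Evaluate one explicit train/test split
#'
#' Fits MFPCA and the classifier on the training rows only, then scores
#' the test rows. Exposed separately from \code{\link{repeatEvaluate}} so
#' a single split is reproducible in isolation and so the train-only
#' contract is directly testable.
#'
#' @param prep output of \code{\link{prepareCohortData}}.
#' @param task one of \code{"focal_vs_diffuse"}, \code{"focal_vs_nonfocal"},
#'   \code{"three_class"}.
#' @param method one of \code{"ppgi_cutoff"}, \code{"penalized_logistic"},
#'   \code{"random_forest"}; the cut-off method applies only to binary
#'   tasks and yields no probability scores (its AUC is \code{NA}).
#' @param trainIdx,testIdx integer indices into the task's record subset
#'   (see \code{taskIndex} in the return value of this function /
#'   \code{\link{repeatEvaluate}}); rows are relative to the vessels kept
#'   for the task.
#' @param includePpgi use the 13-feature PPGi model instead of the
#'   12-feature muFR model (ignored by the cut-off method).
#' @param seed seed for fold assignment / forest growth.
#' @param cutoff PPGi cut-off for the cut-off method (default 0.78).
#' @param alpha,nFolds,selectionRule passed to
#'   \code{\link{fitPenalizedLogistic}}.
#' @param nTrees passed to \code{\link{fitRandomForest}}.
#' @param labelsOverride optional replacement for the task's labels
#'   (testing hook for the leakage guard; training rows must agree with
#'   the stored labels).
#' @return list with per-split \code{metrics} (named list), the test
#'   \code{predictions}, the test probability matrix \code{proba} (NULL
#'   for the cut-off method), and \code{classLevels}.
#' @export
evaluateSplit <- function(prep, task, method, trainIdx, testIdx,
                          includePpgi = TRUE, seed = 1, cutoff = 0.78,
                          alpha = 0.5, nFolds = 10,
                          selectionRule = "min", nTrees = 500,
                          labelsOverride = NULL) {
  task <- match.arg(task, .TASKS)
  method <- match.arg(method, .METHODS)
  keep <- .taskKeep(prep$labels, task)
  y <- .taskLabels(prep$labels[keep], task)
  if (!is.null(labelsOverride)) y <- factor(labelsOverride, levels = levels(y))
  sub <- .subsetPrep(prep, keep)
  positive <- "focal"

  if (method == "ppgi_cutoff") {
    if (task == "three_class")
      .stopf("the PPGi cut-off rule is binary and cannot address the three-class task")
    raw <- classifyByPpgiCutoff(sub$indices$ppgi[testIdx], cutoff = cutoff)
    negLab <- setdiff(levels(y), positive)
    pred <- ifelse(raw == "focal", positive, negLab)
    proba <- NULL
  } else {
    mf <- fitMfpca(.sampleRows(sub$sample, trainIdx), nComponents = 3)
    scores <- mfpcaScores(mf, sub$sample)
    X <- buildFeatureMatrix(sub$cohort, scores, includePpgi = includePpgi,
                            indices = sub$indices)
    fit <- if (method == "penalized_logistic")
      fitPenalizedLogistic(X[trainIdx, , drop = FALSE], y[trainIdx],
                           alpha = alpha, nFolds = nFolds, seed = seed,
                           selectionRule = selectionRule, task = task)
    else
      fitRandomForest(X[trainIdx, , drop = FALSE], y[trainIdx],
                      nTrees = nTrees, seed = seed, task = task)
    proba <- predictProba(fit, X[testIdx, , drop = FALSE])
    pred <- fit@classLevels[max.col(proba, ties.method = "first")]
  }

  truth <- as.character(y[testIdx])
  metrics <- if (task == "three_class") {
    cm <- tabulateConfusion(truth, pred, classOrder = levels(y))
    auc <- oneVsRestAuc(proba, truth)
    out <- list(accuracy = sum(diag(cm@counts)) / sum(cm@counts))
    for (cl in levels(y)) {
      bt <- ifelse(truth == cl, cl, "rest")
      bp <- ifelse(pred == cl, cl, "rest")
      bm <- confusionMetrics(tabulateConfusion(bt, bp,
                                               classOrder = c("rest", cl)), cl)
      out[[paste0("sensitivity_", cl)]] <- bm$sensitivity
      out[[paste0("specificity_", cl)]] <- bm$specificity
      out[[paste0("auc_", cl)]] <- unname(auc[cl])
    }
    out
  } else {
    cm <- tabulateConfusion(truth, pred, classOrder = levels(y))
    out <- confusionMetrics(cm, positive)
    out$auc <- if (is.null(proba)) NA_real_ else
      rocAuc(proba[, positive], truth, positiveClass = positive)
    out
  }
  list(metrics = metrics, predictions = pred, proba = proba,
       classLevels = levels(y), taskIndex = which(keep))
}

.taskKeep <- function(labels4, task) {
  if (task == "focal_vs_diffuse") labels4 %in% c("focal", "diffuse")
  else rep(TRUE, length(labels4))
}

.subsetPrep <- function(prep, keep) {
  if (all(keep)) return(prep)
  list(cohort = new("VesselCohort", records = prep$cohort@records[keep],
                    covariates = prep$cohort@covariates[keep, , drop = FALSE]),
       sample = .sampleRows(prep$sample, which(keep)),
       indices = prep$indices[keep, , drop = FALSE],
       labels = prep$labels[keep])
}

#' Repeated train/test split evaluation
#'
#' Repeats the full pipeline \code{nIterations} times: stratified
#' splitting (by the four-class label), MFPCA refitted on the training
#' vessels only, classifier fitting, held-out scoring, and
#' confusion/ROC metrics. Iteration \code{i} uses seed
#' \code{baseSeed + i}, making any single iteration reproducible in
#' isolation; test sets missing a task class are re-drawn (with a count
#' kept in the report).
#'
#' @param cohort a labelled \linkS4class{VesselCohort}, or the output of
#'   \code{\link{prepareCohortData}}.
#' @param task,method,includePpgi,cutoff,alpha,nFolds,selectionRule,nTrees
#'   see \code{\link{evaluateSplit}}.
#' @param nIterations number of random splits (default 500).
#' @param baseSeed seed base (default 1).
#' @param trainFraction training fraction (default 0.75).
#' @param nGrid registration grid size when \code{cohort} is a
#'   \linkS4class{VesselCohort}.
#' @return an \linkS4class{EvaluationReport}; the summary holds the
#'   per-metric mean and 95\% percentile confidence interval across
#'   iterations.
#' @export
repeatEvaluate <- function(cohort, task, method, includePpgi = TRUE,
                           nIterations = 500, baseSeed = 1,
                           trainFraction = 0.75, cutoff = 0.78,
                           alpha = 0.5, nFolds = 10, selectionRule = "min",
                           nTrees = 500, nGrid = 101) {
  task <- match.arg(task, .TASKS)
  method <- match.arg(method, .METHODS)
  prep <- if (is(cohort, "VesselCohort"))
    prepareCohortData(cohort, nGrid = nGrid) else cohort
  keep <- .taskKeep(prep$labels, task)
  strat <- prep$labels[keep]
  taskLv <- levels(.taskLabels(strat, task))
  rows <- vector("list", nIterations)
  redraws <- 0L
  for (i in seq_len(nIterations)) {
    seedI <- baseSeed + i
    attempt <- 0L
    repeat {
      sp <- splitData(strat, trainFraction = trainFraction,
                      stratify = TRUE, seed = seedI + attempt * 1000003L)
      testLv <- unique(as.character(.taskLabels(strat[sp$test], task)))
      if (length(testLv) == length(taskLv)) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 50L)
        .stopf("repeatEvaluate: cannot draw a test set containing every class")
    }
    res <- evaluateSplit(prep, task, method, sp$train, sp$test,
                         includePpgi = includePpgi, seed = seedI,
                         cutoff = cutoff, alpha = alpha, nFolds = nFolds,
                         selectionRule = selectionRule, nTrees = nTrees)
    rows[[i]] <- as.data.frame(res$metrics)
  }
  iter <- do.call(rbind, rows)
  summ <- .summarizeIterations(iter)
  new("EvaluationReport", task = task,
      method = if (method == "ppgi_cutoff") method else
        paste0(method, if (includePpgi) "_ppgi" else "_mufr"),
      iterations = iter, summaryTable = summ,
      nIterations = as.integer(nIterations),
      baseSeed = as.integer(baseSeed), redraws = redraws)
}

# Mean and 95% CI per metric column. Percentile CIs by default; the
# normal approximation is available for comparison.
.summarizeIterations <- function(iter, ciType = c("percentile", "normal")) {
  ciType <- match.arg(ciType)
  rows <- lapply(names(iter), function(nm) {
    x <- iter[[nm]]
    ok <- !is.na(x)
    if (!any(ok)) return(data.frame(metric = nm, mean = NA_real_,
                                    ci_lower = NA_real_, ci_upper = NA_real_))
    x <- x[ok]
    m <- mean(x)
    ci <- if (ciType == "percentile")
      stats::quantile(x, c(0.025, 0.975), names = FALSE)
    else m + c(-1.96, 1.96) * stats::sd(x) / sqrt(length(x))
    data.frame(metric = nm, mean = m, ci_lower = min(ci[1L], m),
               ci_upper = max(ci[2L], m))
  })
  do.call(rbind, rows)
}

#' Machine-readable twin of an evaluation report
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeReportJson <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  s <- report@summaryTable
  obj <- list(task = report@task, method = report@method,
              n_iterations = report@nIterations,
              base_seed = report@baseSeed, redraws = report@redraws,
              metrics = stats::setNames(lapply(seq_len(nrow(s)), function(i)
                list(mean = s$mean[i], ci_lower = s$ci_lower[i],
                     ci_upper = s$ci_upper[i])), s$metric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
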