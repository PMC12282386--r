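## Classifiers over the 12/13-feature vectors: elastic-net penalized
## logistic regression (binomial or multinomial) with cross-validated
## penalty selection, and a bagged random forest. Both are deterministic
## given the seed.

#' @importFrom glmnet cv.glmnet glmnet
#' @importFrom randomForest randomForest
NULL

# Stratified, seeded fold assignment.
.stratifiedFolds <- function(y, nFolds) {
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  foldid
}

#' Elastic-net penalized logistic regression
#'
#' Standardizes features, fits the elastic-net regularization path
#' (penalty \eqn{\lambda[\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2]}
#' on the average negative log-likelihood) over a decreasing
#' log-spaced grid from the smallest all-slopes-zero penalty, and selects
#' the penalty by stratified n-fold cross-validated deviance. Three-class
#' problems use the symmetric multinomial likelihood. Constant feature
#' columns are dropped with a warning.
#'
#' @param X numeric feature matrix.
#' @param y class labels (factor or character, >= 2 classes present).
#' @param alpha elastic-net mixing in [0, 1] (default 0.5; the value is a
#'   config knob, not a reported quantity).
#' @param nFolds cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param selectionRule \code{"min"} (default) for the deviance-minimizing
#'   penalty or \code{"1se"} for the one-standard-error rule.
#' @param nLambda,lambdaMinRatio grid size (default 100) and ratio of the
#'   smallest to the largest penalty (default 1e-4).
#' @param task free-text task tag stored in the result.
#' @return a \linkS4class{FitResult}.
#' @export
fitPenalizedLogistic <- function(X, y, alpha = 0.5, nFolds = 10, seed = 1,
                                 selectionRule = c("min", "1se"),
                                 nLambda = 100, lambdaMinRatio = 1e-4,
                                 task = "unspecified") {
  selectionRule <- match.arg(selectionRule)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    .stopf("fitPenalizedLogistic: need at least 2 classes in y")
  if (nrow(X) < nFolds)
    .stopf("fitPenalizedLogistic: fewer observations than folds")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant feature column(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  cvfit <- .withSeed(seed, {
    foldid <- .stratifiedFolds(y, nFolds)
    glmnet::cv.glmnet(X, y, family = fam, alpha = alpha, foldid = foldid,
                      nlambda = nLambda, lambda.min.ratio = lambdaMinRatio,
                      standardize = TRUE, type.measure = "deviance")
  })
  sel <- if (selectionRule == "min") cvfit$lambda.min else cvfit$lambda.1se
  path <- data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                     cvsd = cvfit$cvsd, nzero = as.integer(cvfit$nzero))
  new("FitResult", algorithm = "penalized_logistic", task = task,
      classLevels = levels(y), featureNames = colnames(X),
      fit = cvfit,
      standardization = list(mean = colMeans(X), sd = sds),
      selectedLambda = sel, alpha = alpha, cvPath = path)
}

#' Random forest classifier
#'
#' Bootstrap-aggregated decision trees with \code{sqrt(p)} candidate
#' features per split and out-of-bag class-probability estimates.
#' Deterministic given the seed.
#'
#' @param X numeric feature matrix.
#' @param y class labels (>= 2 classes present).
#' @param nTrees number of trees (default 500).
#' @param seed RNG seed.
#' @param task free-text task tag stored in the result.
#' @return a \linkS4class{FitResult}; the out-of-bag probability matrix is
#'   available as \code{fitted(result@fit)$votes} equivalent via
#'   \code{result@fit$votes}.
#' @export
fitRandomForest <- function(X, y, nTrees = 500, seed = 1,
                            task = "unspecified") {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    .stopf("fitRandomForest: need at least 2 classes in y")
  rf <- .withSeed(seed,
    randomForest::randomForest(x = X, y = y, ntree = nTrees,
                               mtry = max(1L, floor(sqrt(ncol(X))))))
  new("FitResult", algorithm = "random_forest", task = task,
      classLevels = levels(y), featureNames = colnames(X),
      fit = rf, standardization = list(),
      selectedLambda = NA_real_, alpha = NA_real_,
      cvPath = data.frame())
}

#' Class-probability predictions
#'
#' Predicted class probabilities in the fixed class order of the fit
#' (\code{fit@classLevels}); rows sum to 1. The predicted label used by
#' all downstream metrics is the probability argmax (equivalently the
#' 0.5 threshold in the binary case).
#'
#' @param fit a \linkS4class{FitResult}.
#' @param X feature matrix with the training columns.
#' @return subjects x classes probability matrix.
#' @export
predictProba <- function(fit, X) {
  stopifnot(is(fit, "FitResult"))
  X <- as.matrix(X)
  miss <- setdiff(fit@featureNames, colnames(X))
  if (length(miss))
    .stopf("predictProba: X lacks training feature(s): %s",
           paste(miss, collapse = ", "))
  X <- X[, fit@featureNames, drop = FALSE]
  k <- length(fit@classLevels)
  if (fit@algorithm == "penalized_logistic") {
    pr <- stats::predict(fit@fit, newx = X, s = fit@selectedLambda,
                         type = "response")
    P <- if (k == 2L) cbind(1 - pr[, 1L], pr[, 1L]) else pr[, , 1L]
  } else {
    P <- stats::predict(fit@fit, X, type = "prob")
  }
  P <- as.matrix(P)
  colnames(P) <- if (ncol(P) == k && fit@algorithm == "penalized_logistic" &&
                     k == 2L) fit@classLevels else colnames(P)
  P <- P[, fit@classLevels, drop = FALSE]
  P / rowSums(P)
  }

#' Predicted class labels
#'
#' @param fit a \linkS4class{FitResult}.
#' @param X feature matrix.
#' @return character vector of predicted labels (probability argmax).
#' @export
predictLabel <- function(fit, X) {
  P <- predictProba(fit, X)
  fit@classLevels[max.col(P, ties.method = "first")]
}

#' Coefficients of a penalized logistic fit
#'
#' Returns the coefficients at the selected penalty, on the original
#' feature scale (as fitted) or rescaled to the standardized scale
#' (\code{beta_std = beta * sd(x)}, with the intercept shifted
#' accordingly); both parameterizations define the same decision function.
#'
#' @param fit a \linkS4class{FitResult} from
#'   \code{\link{fitPenalizedLogistic}} (binary).
#' @param scale \code{"original"} or \code{"standardized"}.
#' @return named numeric vector (intercept first).
#' @export
logisticCoefficients <- function(fit, scale = c("original", "standardized")) {
  scale <- match.arg(scale)
  stopifnot(fit@algorithm == "penalized_logistic",
            length(fit@classLevels) == 2L)
  cf <- as.matrix(stats::coef(fit@fit, s = fit@selectedLambda))[, 1L]
  if (scale == "original") return(cf)
  mu <- fit@standardization$mean
  sds <- fit@standardization$sd
  beta <- cf[-1L]
  c(`(Intercept)` = unname(cf[1L] + sum(beta * mu)), beta * sds)
}

#' L1 norm of the coefficient path
#'
#' For checking the regularization path: the coefficient L1 norm along
#' the fitted lambda grid (summed over classes for multinomial fits).
#'
#' @param fit a \linkS4class{FitResult} from
#'   \code{\link{fitPenalizedLogistic}}.
#' @return data.frame with \code{lambda} and \code{l1norm}, lambda
#'   decreasing.
#' @export
coefficientPathNorms <- function(fit) {
  stopifnot(fit@algorithm == "penalized_logistic")
  g <- fit@fit$glmnet.fit
  b <- g$beta
  l1 <- if (is.list(b))
    Reduce(`+`, lapply(b, function(m) colSums(abs(as.matrix(m)))))
  else colSums(abs(as.matrix(b)))
  data.frame(lambda = g$lambda, l1norm = as.numeric(l1))
}
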