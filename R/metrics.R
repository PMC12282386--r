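#' Build a confusion matrix from truth and predictions
#'
#' @param truth,predicted label vectors of equal length.
#' @param classOrder class labels fixing row/column order (default: sorted
#'   union of observed labels).
#' @return a \linkS4class{ConfusionMatrix} (rows = truth).
#' @export
tabulateConfusion <- function(truth, predicted,
                              classOrder = sort(unique(c(truth, predicted)))) {
  stopifnot(length(truth) == length(predicted))
  tab <- table(factor(truth, levels = classOrder),
               factor(predicted, levels = classOrder))
  confusionMatrix(unclass(as.matrix(tab)), classOrder)
}

#' Confusion-derived metrics for a binary problem
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value from a 2x2 confusion matrix. Ratios with a zero denominator are
#' reported as \code{NA}, never as 0.
#'
#' @param cm a 2x2 \linkS4class{ConfusionMatrix}.
#' @param positiveClass which class is "positive".
#' @return named list: \code{accuracy, sensitivity, specificity, ppv,
#'   npv}.
#' @examples
#' cm <- confusionMatrix(matrix(c(72, 76, 2, 84), 2,
#'                       dimnames = list(c("diffuse", "focal"),
#'                                       c("diffuse", "focal"))))
#' confusionMetrics(cm, "focal")  # accuracy 0.667, sensitivity 0.525, ...
#' @export
confusionMetrics <- function(cm, positiveClass) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  if (nrow(m) != 2L)
    .stopf("confusionMetrics: a 2x2 matrix is required")
  if (!positiveClass %in% cm@classOrder)
    .stopf("confusionMetrics: unknown positive class '%s'", positiveClass)
  pos <- match(positiveClass, cm@classOrder)
  neg <- 3L - pos
  tp <- m[pos, pos]; fn <- m[pos, neg]
  tn <- m[neg, neg]; fp <- m[neg, pos]
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  list(accuracy = rat(tp + tn, tp + tn + fp + fn),
       sensitivity = rat(tp, tp + fn),
       specificity = rat(tn, tn + fp),
       ppv = rat(tp, tp + fp),
       npv = rat(tn, tn + fn))
}

#' Area under the ROC curve
#'
#' Computed by the tie-corrected Mann-Whitney rank formula, which equals
#' the trapezoid area under the empirical ROC curve.
#'
#' @param scores positive-class scores or probabilities.
#' @param labels binary truth (logical, or labels with
#'   \code{positiveClass} naming the positive one).
#' @param positiveClass the positive label when \code{labels} is not
#'   logical.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels, positiveClass = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positiveClass))
      .stopf("rocAuc: positiveClass required for non-logical labels")
    labels <- labels == positiveClass
  }
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    .stopf("rocAuc: both classes must be present")
  r <- rank(scores)              # midranks handle ties
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest AUC for a multiclass problem
#'
#' For each class, the \code{\link{rocAuc}} of that class's probability
#' column against the binarized truth.
#'
#' @param probMatrix subjects x classes probability matrix with class
#'   column names.
#' @param labels truth labels; every class column must be present in the
#'   truth.
#' @return named numeric vector of per-class AUCs.
#' @export
oneVsRestAuc <- function(probMatrix, labels) {
  probMatrix <- as.matrix(probMatrix)
  cls <- colnames(probMatrix)
  if (is.null(cls)) .stopf("oneVsRestAuc: probMatrix needs class column names")
  miss <- setdiff(cls, unique(labels))
  if (length(miss))
    .stopf("oneVsRestAuc: class(es) absent from truth: %s",
           paste(miss, collapse = ", "))
  vapply(cls, function(cl) rocAuc(probMatrix[, cl], labels == cl),
         numeric(1))
}

#' Empirical ROC curve coordinates
#'
#' @param scores positive-class scores.
#' @param labels binary truth (logical or with \code{positiveClass}).
#' @param positiveClass positive label for non-logical truth.
#' @return data.frame with \code{threshold}, \code{fpr}, \code{tpr},
#'   ordered from (0,0) to (1,1).
#' @export
rocCurve <- function(scores, labels, positiveClass = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positiveClass))
      .stopf("rocCurve: positiveClass required for non-logical labels")
    labels <- labels == positiveClass
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(labels); nn <- sum(!labels)
  out <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / nn, tpr = sum(pred & labels) / np)
  }, numeric(2)))
  data.frame(threshold = thr, fpr = out[, "fpr"], tpr = out[, "tpr"])
}
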