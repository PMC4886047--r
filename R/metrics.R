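# Diagnostic performance metrics. The positive class defaults to Ben: the
# clinically relevant question for an undetermined (THY3) report is whether
# the model correctly detects benignity.

#' Compute diagnostic classification metrics
#'
#' Builds the 2x2 confusion matrix and reports accuracy, sensitivity,
#' specificity, positive and negative predictive values, and ROC AUC.
#' Undefined ratios (zero denominators) are reported as `NA`, never 0.
#'
#' AUC is the rank-based (Mann-Whitney) area computed from decision values
#' oriented towards the positive class when they are supplied; with hard
#' labels only it equals `(sensitivity + specificity) / 2`.
#'
#' @param predicted,truth Equal-length label vectors over `{"Ben", "PTC"}`.
#' @param positive_class The class treated as positive (default `"Ben"`).
#' @param decision_values Optional numeric scores; larger values must favour
#'   Ben (as returned by [predict.trained_classifier()]). They are flipped
#'   internally if `positive_class = "PTC"`.
#' @return An object of class `performance_report`: confusion matrix,
#'   the five ratio metrics, `auc`, `positive_class` and `n`.
#' @export
compute_metrics <- function(predicted, truth, positive_class = "Ben",
                            decision_values = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` differ in length", call. = FALSE)
  }
  vocab <- c("Ben", "PTC")
  bad <- setdiff(unique(c(predicted, truth)), vocab)
  if (length(bad) > 0L) {
    stop("labels outside the Ben/PTC vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  positive_class <- match.arg(positive_class, vocab)
  negative_class <- setdiff(vocab, positive_class)

  tp <- sum(predicted == positive_class & truth == positive_class)
  tn <- sum(predicted == negative_class & truth == negative_class)
  fp <- sum(predicted == positive_class & truth == negative_class)
  fn <- sum(predicted == negative_class & truth == positive_class)

  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(predicted = c(positive_class,
                                                    negative_class),
                                      truth = c(positive_class,
                                                negative_class)))

  sensitivity <- .safe_ratio(tp, tp + fn)
  specificity <- .safe_ratio(tn, tn + fp)

  scores <- if (is.null(decision_values)) {
    as.numeric(predicted == positive_class)
  } else {
    if (length(decision_values) != length(truth)) {
      stop("`decision_values` length mismatch", call. = FALSE)
    }
    if (positive_class == "PTC") -decision_values else decision_values
  }
  npos <- tp + fn
  nneg <- tn + fp
  auc <- if (npos == 0L || nneg == 0L) {
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[truth == positive_class]) - npos * (npos + 1) / 2) / (npos * nneg)
  }

  structure(list(confusion = confusion,
                 accuracy = .safe_ratio(tp + tn, length(truth)),
                 sensitivity = sensitivity,
                 specificity = specificity,
                 ppv = .safe_ratio(tp, tp + fp),
                 npv = .safe_ratio(tn, tn + fn),
                 auc = auc,
                 positive_class = positive_class,
                 n = length(truth)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> n = %d, positive class = %s\n",
              x$n, x$positive_class))
  print(x$confusion)
  cat(sprintf(
    "accuracy %.3f | sensitivity %.3f | specificity %.3f | PPV %.3f | NPV %.3f | AUC %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv, x$auc))
  invisible(x)
}

#' Flatten a performance report to a named numeric vector
#' @param report A [compute_metrics()] report.
#' @return Named numeric vector of the six headline metrics.
#' @export
metrics_vector <- function(report) {
  stopifnot(inherits(report, "performance_report"))
  c(accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, ppv = report$ppv, npv = report$npv,
    auc = report$auc)
}
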