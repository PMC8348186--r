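# Evaluation metrics: accuracy, AUC, confusion matrix with per-class
# TPR/FNR, prediction speed.

#' Binary AUC from ranked scores
#'
#' Mann-Whitney formulation: probability that a random positive outranks a
#' random negative, with ties counting one half.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param is_positive Logical vector of the same length.
#' @return AUC in [0, 1]; `NA` if either class is absent.
#' @export
auc_binary <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# macro one-vs-rest AUC from a per-class score matrix
auc_multiclass <- function(scores, y_true) {
  classes <- colnames(scores)
  present <- intersect(classes, unique(y_true))
  if (length(present) < 2) return(NA_real_)
  aucs <- vapply(present, function(c) auc_binary(scores[, c], y_true == c),
                 numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model A fitted classifier from [train_classifier()] (the `model`
#'   element) or [fit_classifier] output.
#' @param X_test Feature matrix.
#' @param y_test True labels; every label must be known to the model.
#' @param positive_class For binary problems, the class treated as
#'   positive for the AUC ranking (defaults to the last sorted class).
#' @param cv_accuracy Optional training (cross-validation) accuracy to
#'   carry into the report.
#' @return An object of class `evaluation_report`: list with
#'   `cv_accuracy`, `test_accuracy` (percent), `auc`, `confusion` (rows =
#'   true classes, columns = predicted), `tpr_per_class`, `fnr_per_class`,
#'   `n_test`.
#' @export
evaluate_classifier <- function(model, X_test, y_test, positive_class = NULL,
                                cv_accuracy = NA_real_) {
  X_test <- as.matrix(X_test)
  if (nrow(X_test) == 0) stop("test set is empty")
  y_test <- as.character(y_test)
  unknown <- setdiff(unique(y_test), model$classes)
  if (length(unknown) > 0)
    stop("test labels unseen in training: ", paste(unknown, collapse = ", "))
  out <- predict_model(model, X_test, scores = TRUE)
  pred <- out$class
  acc <- 100 * mean(pred == y_test)
  classes <- model$classes
  confusion <- table(factor(y_test, classes), factor(pred, classes))
  names(dimnames(confusion)) <- c("true", "predicted")
  rs <- rowSums(confusion)
  tpr <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  auc <- if (length(classes) == 2) {
    pos <- if (is.null(positive_class)) classes[2] else positive_class
    if (!pos %in% classes) stop("positive_class not among model classes")
    auc_binary(out$scores[, pos], y_test == pos)
  } else {
    auc_multiclass(out$scores, y_test)
  }
  structure(list(cv_accuracy = cv_accuracy, test_accuracy = acc, auc = auc,
                 confusion = confusion,
                 tpr_per_class = tpr, fnr_per_class = 1 - tpr,
                 n_test = length(y_test)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> cv %.1f%% | test %.1f%% | AUC %s | n=%d\n",
              x$cv_accuracy, x$test_accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$n_test))
  invisible(x)
}

#' Prediction speed in observations per second
#'
#' Median wall-clock throughput of `predict` over repeated timings.
#' Hardware-dependent; reported but never asserted on.
#'
#' @param model A fitted classifier.
#' @param X Feature matrix to predict.
#' @param repetitions Number of timing repetitions (>= 3).
#' @return Observations per second (median over repetitions).
#' @export
prediction_speed <- function(model, X, repetitions = 5L) {
  if (nrow(as.matrix(X)) == 0) stop("cannot time prediction on empty input")
  if (repetitions < 3) stop("repetitions must be >= 3")
  # repeat the call inside each timing window until it is long enough to
  # measure reliably against clock granularity
  inner <- 1L
  repeat {
    t0 <- proc.time()[["elapsed"]]
    for (j in seq_len(inner)) predict_model(model, X, scores = FALSE)
    if (proc.time()[["elapsed"]] - t0 >= 0.02 || inner >= 4096L) break
    inner <- inner * 4L
  }
  times <- vapply(seq_len(repetitions), function(i) {
    t0 <- proc.time()[["elapsed"]]
    for (j in seq_len(inner)) predict_model(model, X, scores = FALSE)
    max(proc.time()[["elapsed"]] - t0, 1e-9)
  }, numeric(1))
  inner * nrow(as.matrix(X)) / stats::median(times)
}

#' Normalise prediction speeds against the fastest
#'
#' Divides each entry by the maximum so the fastest classifier scores
#' exactly 1.
#'
#' @param speeds Numeric vector of speeds (observations/second).
#' @return Vector of ratios in (0, 1].
#' @export
normalize_speeds <- function(speeds) {
  if (length(speeds) == 0) stop("no speeds to normalise")
  speeds / max(speeds)
}

#' Adjacency share of confusion-matrix errors
#'
#' Fraction of the off-diagonal confusion mass that falls within
#' `window` positions of the diagonal under a given class ordering. High
#' values mean misclassifications land in neighbouring severity classes.
#'
#' @param confusion Square confusion matrix (rows = true classes).
#' @param ordering Character vector giving the class order (default: the
#'   row order of `confusion`).
#' @param window Band half-width counted as "adjacent".
#' @return Fraction in [0, 1]; `NA` when there are no errors.
#' @export
confusion_adjacency <- function(confusion, ordering = rownames(confusion),
                                window = 2L) {
  stopifnot(all(rownames(confusion) %in% ordering))
  m <- confusion[ordering, ordering]
  pos <- abs(row(m) - col(m))
  off <- pos > 0
  if (sum(m[off]) == 0) return(NA_real_)
  sum(m[off & pos <= window]) / sum(m[off])
}
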