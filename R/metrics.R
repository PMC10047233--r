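#' Confusion matrix from labels and predictions
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,predicted factors, integer class indices, or character
#'   labels of equal length.
#' @param levels class levels; defaults to the union of observed values
#'   (or [label_names()] when both inputs are one of those labels).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  if (is.null(levels)) {
    obs <- unique(c(as.character(truth), as.character(predicted)))
    levels <- if (all(obs %in% label_names())) label_names() else sort(obs)
  }
  t_ <- factor(as.character(truth), levels = levels)
  p_ <- factor(as.character(predicted), levels = levels)
  cm <- unclass(table(t_, p_, dnn = c("truth", "predicted")))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

check_cm <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) < 1) stop("empty confusion matrix", call. = FALSE)
  if (any(cm < 0)) stop("negative confusion-matrix counts", call. = FALSE)
  cm
}

#' Categorical accuracy
#'
#' Correct predictions (the trace) over the total count.
#' @param cm square confusion matrix (rows = truth).
#' @return Fraction in `[0, 1]`.
#' @export
categorical_accuracy <- function(cm) {
  cm <- check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Micro- and macro-averaged F1 scores
#'
#' Micro precision/recall pool true/false positives and false negatives
#' over the classes; macro averages per-class precision and recall before
#' taking the harmonic mean. For single-label multiclass data micro-F1
#' equals categorical accuracy. Per-class 0/0 ratios entering the macro
#' averages are defined as 0, with a warning.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return Named numeric vector `c(f1_micro =, f1_macro =)`.
#' @export
f1_scores <- function(cm) {
  cm <- check_cm(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prc_micro <- sum(tp) / sum(tp + fp)
  rec_micro <- sum(tp) / sum(tp + fn)
  safe_ratio <- function(num, den) {
    bad <- den == 0
    if (any(bad))
      warning("undefined per-class ratio (0/0) set to 0", call. = FALSE)
    out <- numeric(length(num))
    out[!bad] <- num[!bad] / den[!bad]
    out
  }
  prc_macro <- mean(safe_ratio(tp, tp + fp))
  rec_macro <- mean(safe_ratio(tp, tp + fn))
  hm <- function(a, b) if (a + b == 0) 0 else 2 * a * b / (a + b)
  c(f1_micro = hm(prc_micro, rec_micro), f1_macro = hm(prc_macro, rec_macro))
}

#' Multiclass Matthews correlation coefficient
#'
#' The N-class MCC
#' \deqn{\mathrm{MCC} = \frac{cS - \sum_i p_i t_i}
#'   {\sqrt{(S^2 - \sum_i p_i^2)(S^2 - \sum_i t_i^2)}}}
#' with `c` the correctly predicted count, `S` the total, `t_i` the true
#' and `p_i` the predicted class totals. Bounded in `[-1, 1]`; a zero
#' denominator (e.g. a constant predictor) yields 0 with a warning.
#'
#' @param cm square confusion matrix (rows = truth).
#' @return Coefficient in `[-1, 1]`.
#' @export
mcc_multiclass <- function(cm) {
  cm <- check_cm(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_ <- rowSums(cm)
  p_ <- colSums(cm)
  den2 <- (s^2 - sum(p_^2)) * (s^2 - sum(t_^2))
  if (den2 <= 0) {
    warning("MCC denominator is zero; returning 0", call. = FALSE)
    return(0)
  }
  (c_ * s - sum(p_ * t_)) / sqrt(den2)
}

#' Standard evaluation report
#'
#' The four multiclass metrics in their conventional report order.
#' @param cm square confusion matrix (rows = truth).
#' @return Named numeric vector with elements `Categorical Accuracy`,
#'   `F1 Micro`, `F1 Macro` and `MCC`.
#' @export
metrics_report <- function(cm) {
  f1 <- f1_scores(cm)
  c("Categorical Accuracy" = categorical_accuracy(cm),
    "F1 Micro" = unname(f1["f1_micro"]),
    "F1 Macro" = unname(f1["f1_macro"]),
    "MCC" = mcc_multiclass(cm))
}
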