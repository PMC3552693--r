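#' Confusion matrix for two-class predictions
#'
#' Cross-tabulates true against predicted classes with +1 (cancer) as the
#' positive class: `tp` = true positives, `fp` = false positives, `fn` =
#' false negatives, `tn` = true negatives.
#'
#' @param truth True class vector in \{-1, +1\}.
#' @param pred Predicted class vector in \{-1, +1\}, same length.
#' @return An object of class `confusion` (a named list of the four counts).
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length", class = "panelselect_length")
  }
  if (!all(truth %in% c(-1, 1)) || !all(pred %in% c(-1, 1))) {
    abort("labels must be -1 or +1", class = "panelselect_bad_y")
  }
  confusion_counts(
    tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == -1 & pred == 1),
    fn = sum(truth == 1 & pred == -1),
    tn = sum(truth == -1 & pred == -1)
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> (+1 = cancer)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
    dimnames = list(predicted = c("cancer", "normal"),
      truth = c("cancer", "normal")))
  print(m)
  invisible(x)
}

#' @method tidy confusion
#' @export
tidy.confusion <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined: zero denominator", what))
    return(NaN)
  }
  num / den
}

#' Classification performance measures
#'
#' The four closed-form measures derived from a confusion matrix:
#' sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/(TP+TN+FP+FN).
#' A zero denominator yields `NaN` with a warning rather than an error.
#'
#' @param cm A `confusion` object from [confusion_matrix()].
#' @return A single value in \[0, 1\] (or `NaN`).
#' @export
sensitivity <- function(cm) metric_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(cm) metric_ratio(cm$tn, cm$tn + cm$fp, "specificity")

#' @rdname sensitivity
#' @export
precision <- function(cm) metric_ratio(cm$tp, cm$tp + cm$fp, "precision")

#' @rdname sensitivity
#' @export
accuracy <- function(cm) {
  metric_ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn, "accuracy")
}

#' All four measures as a tidy table
#'
#' @param cm A `confusion` object.
#' @return A tibble with columns `metric` and `value`.
#' @export
classification_metrics <- function(cm) {
  tibble(
    metric = c("sensitivity", "specificity", "precision", "accuracy"),
    value = c(sensitivity(cm), specificity(cm), precision(cm), accuracy(cm))
  )
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the unique decision scores (tied scores move
#' together in a single step) and reports (FPR, TPR) points; the AUC is the
#' trapezoidal integral of the curve, which equals the Mann-Whitney
#' concordant-pair probability with half credit for ties.
#'
#' @param scores Numeric decision scores; larger means more cancer-like.
#' @param truth True class vector in \{-1, +1\}; both classes required.
#' @return `roc_curve()`: a tibble of class `roc_df` with columns
#'   `threshold`, `fpr`, `tpr` (starting at (0, 0)) and the AUC attached as
#'   attribute `auc`. `roc_auc()`: the AUC as a single number.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(-1, 1)))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == -1)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present", class = "panelselect_one_class")
  }
  steps <- tibble(score = scores, pos = truth == 1) |>
    group_by(.data$score) |>
    summarise(np = sum(.data$pos), nn = sum(!.data$pos)) |>
    arrange(desc(.data$score)) |>
    mutate(
      tpr = cumsum(.data$np) / n_pos,
      fpr = cumsum(.data$nn) / n_neg
    )
  pts <- tibble(
    threshold = c(Inf, steps$score),
    fpr = c(0, steps$fpr),
    tpr = c(0, steps$tpr)
  )
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(pts, auc = auc, class = c("roc_df", class(pts)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, truth) {
  attr(roc_curve(scores, truth), "auc")
}

#' Plot an ROC curve
#'
#' @param object A `roc_df` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_df
#' @export
autoplot.roc_df <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}
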