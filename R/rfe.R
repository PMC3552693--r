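to_xy <- function(x, y) {
  if (is.data.frame(x) && identical(names(x)[1], "probe_id")) {
    stopifnot(is.data.frame(y), all(c("sample_id", "y") %in% names(y)))
    X <- t(expr_matrix(x))
    yy <- y$y[match(rownames(X), y$sample_id)]
    if (anyNA(yy)) abort("sample(s) missing a label", class = "panelselect_missing_label")
    list(X = X, y = as.numeric(yy))
  } else {
    list(X = as_feature_matrix(x), y = as.numeric(y))
  }
}

#' One leave-one-out cross-validation pass
#'
#' For each of the n samples, fits an SVM on the remaining n - 1 samples
#' restricted to `features`, records the absolute per-feature ranking weight
#' and whether the held-out sample is misclassified. Weights and errors are
#' summed over the n folds: `W[f] = sum_folds |W_i[f]|`,
#' `E = number of misclassified held-out samples`.
#'
#' The held-out prediction comes from a per-fold SVM with the configured
#' `control$kernel` (RBF by default, as in the final classifier). With
#' `rank_kernel = "linear"` (default) the ranking weights are the primal
#' weights of a linear-kernel SVM fitted to the same fold with the same
#' cost (the |W| criterion is only defined in the primal); when
#' `control$kernel` is itself linear that single fit provides both. With
#' `rank_kernel = "rbf-margin"` the RBF fold model provides both the error
#' and the kernel margin-change ranking criterion.
#'
#' @param x Expression tibble (probes x samples) or samples-by-features
#'   matrix.
#' @param y Label tibble (for an expression tibble) or class vector in
#'   \{-1, +1\}.
#' @param features Feature (probe) IDs to use; default all.
#' @param control An [svm_control()].
#' @return A list with `W` (named numeric, summed absolute weights),
#'   `E` (integer error count), and `n` (number of folds/samples).
#' @export
loocv_pass <- function(x, y, features = NULL, control = svm_control()) {
  d <- to_xy(x, y)
  features <- features %||% colnames(d$X)
  X <- d$X[, features, drop = FALSE]
  yv <- d$y
  n <- nrow(X)
  if (n < 3) abort("need at least 3 samples for LOOCV", class = "panelselect_too_few")
  if (min(sum(yv == 1), sum(yv == -1)) < 2) {
    abort("each class needs >= 2 samples so every leave-one-out fold keeps both classes; provide more data",
      class = "panelselect_too_few")
  }
  W <- stats::setNames(numeric(length(features)), features)
  E <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- yv[-i]
    if (control$rank_kernel == "rbf-margin") {
      fit <- svm_train(Xtr, ytr, control = control, kernel = "rbf")
      w_i <- abs(rbf_margin_criterion(fit, Xtr))
    } else {
      lin <- svm_train(Xtr, ytr, control = control, kernel = "linear")
      w_i <- abs(lin$w)
      fit <- if (control$kernel == "linear") lin else
        svm_train(Xtr, ytr, control = control)
    }
    W[names(w_i)] <- W[names(w_i)] + w_i
    pred <- predict(fit, X[i, , drop = FALSE])
    E <- E + as.integer(pred != yv[i])
  }
  list(W = W, E = E, n = n)
}

#' Cross-validation score
#'
#' The score used to compare feature subsets: error rate times the sample
#' size, i.e. the number of misclassified held-out samples.
#'
#' @param error_count Integer number of misclassified samples, in
#'   \[0, n\].
#' @param n Number of samples, > 0.
#' @return `(error_count / n) * n`.
#' @export
cv_score <- function(error_count, n) {
  stopifnot(n > 0, error_count >= 0, error_count <= n)
  (error_count / n) * n
}

#' SVM recursive feature elimination with leave-one-out cross-validation
#'
#' Backward feature elimination in which each iteration runs a full
#' leave-one-out pass ([loocv_pass()]): per-feature absolute weights and
#' held-out error counts are summed over the n folds, every feature tied at
#' the minimum summed-weight rank is eliminated, and the loop continues
#' while the summed error E does not exceed the previous iteration's value
#' (so elimination proceeds through error plateaus, favouring small
#' panels). The loop therefore exits one step past its best state; the
#' returned panel is the trace iteration attaining the minimum E with the
#' fewest features. At least one feature always survives.
#'
#' The final classifier on the selected panel is refit on all provided
#' samples with `control$kernel` (RBF by default).
#'
#' @inheritParams loocv_pass
#' @return An object of class `panel_selection`: `panel` (selected feature
#'   IDs), `E` and `cv_score` of the selection, `trace` (one row per
#'   iteration: `iteration`, `n_features`, `E`, `cv_score`, plus list
#'   columns `features`, `weights`, `eliminated`), `fit` (the refitted
#'   classifier), `control`, and `n_samples`.
#' @export
svm_rfe_cv <- function(x, y, features = NULL, control = svm_control()) {
  d <- to_xy(x, y)
  features <- features %||% colnames(d$X)
  if (length(features) < 1) {
    abort("no features to select from", class = "panelselect_no_features")
  }
  feats <- features
  pass <- loocv_pass(d$X, d$y, feats, control)
  trace <- list(trace_row(1L, feats, pass, character(0)))
  E0 <- pass$E
  it <- 1L
  while (length(feats) > 1) {
    rkw <- rank(pass$W[feats], ties.method = "min")
    keep <- feats[rkw > 1]
    if (length(keep) == 0) {
      # all features tied at the minimum rank: keep one survivor
      keep <- feats[which.max(pass$W[feats])]
    }
    eliminated <- setdiff(feats, keep)
    feats <- keep
    pass <- loocv_pass(d$X, d$y, feats, control)
    it <- it + 1L
    trace[[it]] <- trace_row(it, feats, pass, eliminated)
    if (pass$E > E0) break
    E0 <- pass$E
  }
  trace <- bind_rows(trace)
  best_e <- min(trace$E)
  sel <- trace |> filter(.data$E == best_e) |> arrange(.data$n_features) |> slice(1)
  panel <- sel$features[[1]]
  fit <- svm_train(d$X[, panel, drop = FALSE], d$y, control = control)
  structure(
    list(
      panel = panel,
      E = sel$E,
      cv_score = cv_score(sel$E, nrow(d$X)),
      trace = trace,
      fit = fit,
      control = control,
      n_samples = nrow(d$X)
    ),
    class = "panel_selection"
  )
}

trace_row <- function(it, feats, pass, eliminated) {
  tibble(
    iteration = it,
    n_features = length(feats),
    E = pass$E,
    cv_score = cv_score(pass$E, pass$n),
    features = list(feats),
    weights = list(pass$W),
    eliminated = list(eliminated)
  )
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf(
    "<panel_selection> %d feature(s), summed LOOCV error E = %d (cv score %g) over %d iterations\n",
    length(x$panel), x$E, x$cv_score, nrow(x$trace)))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy panel_selection
#' @export
tidy.panel_selection <- function(x, ...) {
  x$trace |>
    mutate(
      eliminated = purrr::map_chr(.data$eliminated, paste, collapse = ","),
      selected = .data$n_features == length(x$panel) & .data$E == x$E
    ) |>
    select("iteration", "n_features", "E", "cv_score", "eliminated", "selected")
}

#' @method glance panel_selection
#' @export
glance.panel_selection <- function(x, ...) {
  tibble(
    panel_size = length(x$panel),
    E = x$E,
    cv_score = x$cv_score,
    n_iterations = nrow(x$trace),
    n_samples = x$n_samples,
    kernel = x$control$kernel,
    C = x$control$C
  )
}

#' Tuning-curve plot for a panel selection
#'
#' Cross-validation score against the number of surviving features across
#' the elimination trace, with the selected panel highlighted.
#'
#' @param object A `panel_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_selection
#' @export
autoplot.panel_selection <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_features, y = .data$cv_score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "#b2182b"),
      guide = "none") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Number of surviving features",
      y = "Cross-validation score (summed LOOCV errors)",
      title = "Recursive feature elimination tuning curve") +
    ggplot2::theme_minimal()
}
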