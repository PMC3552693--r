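candidate_ids <- function(candidates) {
  if (is.data.frame(candidates)) candidates$probe_id else as.character(candidates)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

fit_and_score_panel <- function(panel, Xtr, ytr, Xte, control, cv_k = 5) {
  Xp <- Xtr[, panel, drop = FALSE]
  fold <- stratified_folds(ytr, cv_k)
  correct <- 0L
  for (f in seq_len(cv_k)) {
    hold <- fold == f
    if (!any(hold)) next
    m <- svm_train(Xp[!hold, , drop = FALSE], ytr[!hold], control = control)
    correct <- correct + sum(predict(m, Xp[hold, , drop = FALSE]) == ytr[hold])
  }
  fit <- svm_train(Xp, ytr, control = control)
  list(
    cv_accuracy_train = correct / length(ytr),
    scores = decision_scores(fit, Xte[, panel, drop = FALSE]),
    fit = fit
  )
}

#' Enumeration-based panel validation
#'
#' Samples `n_panels` distinct random panels of `panel_size` markers from
#' the candidate set, trains an SVM per panel on the training set (a
#' stratified 5-fold cross-validation estimates training accuracy, then the
#' model is refit on the full training set), scores each on the untouched
#' testing set, and ranks panels by test-set AUC. When the candidate set
#' admits fewer than `n_panels` distinct panels, all subsets are enumerated
#' exhaustively instead.
#'
#' @param train,test Expression tibbles sharing the probe space.
#' @param train_labels,test_labels Matching label tibbles.
#' @param candidates Candidate marker IDs: a character vector or a marker
#'   tibble with a `probe_id` column (e.g. from [select_markers()]).
#' @param panel_size Number of markers per panel (N).
#' @param n_panels Number of random panels to score (M; default 1000).
#' @param seed Integer seed; the sampled panels and CV folds are
#'   deterministic given it.
#' @param control An [svm_control()].
#' @return A tibble of class `panel_ranking` sorted by descending
#'   `auc_test`: `rank`, `panel_id`, `panel` (list column),
#'   `cv_accuracy_train`, `auc_test`, `scores` (list column of test
#'   decision scores). Attributes `n_panels`, `panel_size`, `seed`,
#'   `exhaustive`.
#' @export
enumerate_panels <- function(train, train_labels, test, test_labels,
                             candidates, panel_size, n_panels = 1000,
                             seed = 1, control = svm_control()) {
  cand <- candidate_ids(candidates)
  if (panel_size > length(cand)) {
    abort("panel_size exceeds the number of candidate markers",
      class = "panelselect_bad_panel_size")
  }
  stopifnot(n_panels >= 1)
  Xtr <- t(expr_matrix(train))
  Xte <- t(expr_matrix(test))
  ytr <- train_labels$y[match(rownames(Xtr), train_labels$sample_id)]
  yte <- test_labels$y[match(rownames(Xte), test_labels$sample_id)]
  n_total <- choose(length(cand), panel_size)
  exhaustive <- n_total <= n_panels
  out <- withr::with_seed(seed, {
    panels <- if (exhaustive) {
      apply(combn(cand, panel_size), 2, identity, simplify = FALSE)
    } else {
      seen <- character(0)
      panels <- list()
      while (length(panels) < n_panels) {
        p <- sort(sample(cand, panel_size))
        key <- paste(p, collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        panels[[length(panels) + 1]] <- p
      }
      panels
    }
    purrr::map(panels, function(p) {
      sc <- fit_and_score_panel(p, Xtr, ytr, Xte, control)
      tibble(
        panel = list(p),
        cv_accuracy_train = sc$cv_accuracy_train,
        auc_test = roc_auc(sc$scores, yte),
        scores = list(sc$scores)
      )
    }) |> bind_rows()
  })
  out <- out |>
    mutate(panel_id = dplyr::row_number()) |>
    arrange(desc(.data$auc_test), .data$panel_id) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "panel_id", "panel", "cv_accuracy_train", "auc_test", "scores")
  structure(out,
    n_panels = length(out$panel), panel_size = panel_size, seed = seed,
    exhaustive = exhaustive,
    class = c("panel_ranking", class(out)))
}

#' ROC curves for a set of panels
#'
#' Trains one classifier per panel on the training set, scores the testing
#' set, and returns the per-panel ROC points ready for plotting; one panel
#' (by default the first) can be flagged as the designated panel, e.g. the
#' selected panel against best/worst random panels.
#'
#' @param panels Named list of character vectors of marker IDs.
#' @param train,test Expression tibbles.
#' @param train_labels,test_labels Matching label tibbles.
#' @param control An [svm_control()].
#' @param flag Name or index of the designated panel (default 1).
#' @return A tibble of class `panel_roc_df`: `panel`, `flagged`,
#'   `threshold`, `fpr`, `tpr`, `auc`.
#' @export
compare_panel_rocs <- function(panels, train, train_labels, test, test_labels,
                               control = svm_control(), flag = 1) {
  stopifnot(is.list(panels), length(panels) >= 1)
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- paste0("panel_", seq_along(panels))
  }
  flag_name <- if (is.numeric(flag)) names(panels)[flag] else flag
  Xtr <- t(expr_matrix(train))
  Xte <- t(expr_matrix(test))
  ytr <- train_labels$y[match(rownames(Xtr), train_labels$sample_id)]
  yte <- test_labels$y[match(rownames(Xte), test_labels$sample_id)]
  out <- purrr::imap(panels, function(p, nm) {
    fit <- svm_train(Xtr[, p, drop = FALSE], ytr, control = control)
    roc <- roc_curve(decision_scores(fit, Xte[, p, drop = FALSE]), yte)
    tibble(panel = nm, flagged = identical(nm, flag_name),
      threshold = roc$threshold, fpr = roc$fpr, tpr = roc$tpr,
      auc = attr(roc, "auc"))
  }) |> bind_rows()
  structure(out, class = c("panel_roc_df", class(out)))
}

#' @export
autoplot.panel_roc_df <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$fpr, y = .data$tpr, group = .data$panel,
      colour = .data$flagged, linewidth = .data$flagged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
      colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "#b2182b"),
      labels = c(`FALSE` = "comparison", `TRUE` = "designated"),
      name = NULL) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1),
      guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
      title = "Panel ROC comparison on the testing set") +
    ggplot2::theme_minimal()
}
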