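#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. The configuration is fully
#' serializable ([run_pipeline()] echoes it, with the seeds, into the run
#' directory) because reproducibility of a split-based analysis hinges on
#' recording the split seed.
#'
#' @param log2 Apply the base-2 log-ratio transformation first (only for
#'   raw-scale input; never applied implicitly).
#' @param center Median centering mode: per-`"probe"` (default),
#'   per-`"sample"`, or `"none"`.
#' @param train_fraction,split_seed,stratified Train/test split controls,
#'   see [split_train_test()].
#' @param q_threshold,lambda Screening controls, see [select_markers()] and
#'   [storey_qvalue()].
#' @param svm An [svm_control()].
#' @param enumerate Also run the enumeration validation stage.
#' @param panel_size Panel size for enumeration; default the selected
#'   panel's size.
#' @param n_panels,enum_seed Enumeration controls, see [enumerate_panels()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(log2 = FALSE, center = c("probe", "sample", "none"),
                            train_fraction = 0.5, split_seed = 1,
                            stratified = TRUE, q_threshold = 0.01,
                            lambda = 0.5, svm = svm_control(),
                            enumerate = FALSE, panel_size = NULL,
                            n_panels = 1000, enum_seed = 1) {
  structure(
    list(log2 = log2, center = match.arg(center),
      train_fraction = train_fraction, split_seed = split_seed,
      stratified = stratified, q_threshold = q_threshold, lambda = lambda,
      svm = svm, enumerate = enumerate, panel_size = panel_size,
      n_panels = n_panels, enum_seed = enum_seed),
    class = "pipeline_config"
  )
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

evaluate_fit <- function(fit, expr, labels, panel) {
  X <- t(expr_matrix(expr))[, panel, drop = FALSE]
  y <- labels$y[match(rownames(X), labels$sample_id)]
  scores <- decision_scores(fit, X)
  cm <- confusion_matrix(y, ifelse(scores >= 0, 1, -1))
  roc <- roc_curve(scores, y)
  list(confusion = cm, metrics = classification_metrics(cm),
    auc = attr(roc, "auc"), roc = roc, scores = scores)
}

#' Run the full panel-selection pipeline
#'
#' Orchestrates normalize -> split -> screen -> select -> recursive
#' elimination -> evaluate (-> enumerate), using the testing set for
#' nothing but the final evaluation. A stage log records the MD5 hash of
#' every stage's inputs; the test-set hash is verified absent from the
#' screening and selection stages (data-leakage guard).
#'
#' @param expr Expression tibble (probes x samples).
#' @param labels Label tibble covering all samples.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `screen.tsv`,
#'   `panel.json`, `trace.tsv`, `metrics.json`, `config.yaml`, `log.txt`
#'   (and `ranking.tsv` if enumeration ran) are written there.
#' @return An object of class `panel_pipeline` with elements `config`,
#'   `assignment`, `screen`, `markers`, `selection` (a `panel_selection`),
#'   `evaluation` (`$train`, `$test`: confusion, metrics, AUC, ROC),
#'   `ranking` (or `NULL`), `log`, and `leakage_checked`.
#' @export
run_pipeline <- function(expr, labels, config = pipeline_config(),
                         out_dir = NULL) {
  validate_expression(expr, labels)
  log <- list()
  note <- function(stage, inputs) {
    log[[length(log) + 1]] <<- tibble(stage = stage,
      input = names(inputs), md5 = unname(unlist(inputs)))
  }

  if (isTRUE(config$log2)) expr <- log2_transform(expr)
  if (config$center != "none") expr <- median_center(expr, by = config$center)
  note("normalize", list(expression = md5_of(expr)))

  sp <- split_train_test(expr, labels, train_fraction = config$train_fraction,
    seed = config$split_seed, stratified = config$stratified)
  train_hash <- md5_of(sp$train)
  test_hash <- md5_of(sp$test)
  note("split", list(train = train_hash, test = test_hash))

  screen <- screen_probes(sp$train, sp$train_labels, lambda = config$lambda)
  note("screen", list(train = train_hash))
  markers <- select_markers(screen, q_threshold = config$q_threshold)
  if (nrow(markers) == 0) {
    abort(sprintf("screening stage: empty marker set at q < %g",
      config$q_threshold), class = "panelselect_empty_markers")
  }
  note("select_markers", list(train = train_hash, screen = md5_of(screen)))

  selection <- svm_rfe_cv(sp$train, sp$train_labels,
    features = markers$probe_id, control = config$svm)
  note("rfe_cv", list(train = train_hash, markers = md5_of(markers$probe_id)))

  evaluation <- list(
    train = evaluate_fit(selection$fit, sp$train, sp$train_labels, selection$panel),
    test = evaluate_fit(selection$fit, sp$test, sp$test_labels, selection$panel)
  )
  note("evaluate", list(train = train_hash, test = test_hash))

  ranking <- NULL
  if (isTRUE(config$enumerate)) {
    n_size <- config$panel_size %||% length(selection$panel)
    ranking <- enumerate_panels(sp$train, sp$train_labels, sp$test,
      sp$test_labels, markers, panel_size = n_size,
      n_panels = config$n_panels, seed = config$enum_seed,
      control = config$svm)
    note("enumerate", list(train = train_hash, test = test_hash))
  }

  log_tbl <- bind_rows(log)
  pre_eval <- log_tbl$stage %in% c("screen", "select_markers", "rfe_cv")
  leakage_checked <- !any(log_tbl$md5[pre_eval] == test_hash)
  if (!leakage_checked) {
    abort("data-leakage guard tripped: test-set hash appeared in a selection stage",
      class = "panelselect_leakage")
  }

  res <- structure(
    list(config = config, assignment = sp$assignment, screen = screen,
      markers = markers, selection = selection, evaluation = evaluation,
      ranking = ranking, log = log_tbl, leakage_checked = leakage_checked,
      split = sp),
    class = "panel_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$screen, file.path(out_dir, "screen.tsv"), progress = FALSE)
  readr::write_tsv(tidy(res$selection), file.path(out_dir, "trace.tsv"),
    progress = FALSE)
  jsonlite::write_json(
    list(panel = res$selection$panel, E = res$selection$E,
      cv_score = res$selection$cv_score,
      svm = unclass(res$config$svm)[c("kernel", "C", "rank_kernel")],
      gamma = res$selection$fit$gamma),
    file.path(out_dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  metrics <- lapply(res$evaluation, function(ev) {
    c(tidy(ev$confusion), stats::setNames(as.list(ev$metrics$value),
      ev$metrics$metric), list(auc = ev$auc))
  })
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(res$ranking)) {
    rk <- res$ranking |>
      mutate(panel = purrr::map_chr(.data$panel, paste, collapse = ",")) |>
      select("rank", "panel_id", "panel", "cv_accuracy_train", "auc_test")
    readr::write_tsv(rk, file.path(out_dir, "ranking.tsv"), progress = FALSE)
  }
  cfg <- unclass(res$config)
  cfg$svm <- unclass(cfg$svm)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  readr::write_tsv(res$log, file.path(out_dir, "log.txt"), progress = FALSE)
  invisible(out_dir)
}

#' @export
print.panel_pipeline <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<panel_pipeline> %d markers (q < %g) -> panel of %d; test AUC %.3f, accuracy %.3f\n",
    g$n_markers, x$config$q_threshold, g$panel_size, g$auc_test, g$accuracy_test))
  invisible(x)
}

#' @method glance panel_pipeline
#' @export
glance.panel_pipeline <- function(x, ...) {
  test_m <- x$evaluation$test$metrics
  tibble(
    n_markers = nrow(x$markers),
    expected_false_markers = attr(x$markers, "fpr"),
    panel_size = length(x$selection$panel),
    cv_score = x$selection$cv_score,
    auc_train = x$evaluation$train$auc,
    auc_test = x$evaluation$test$auc,
    accuracy_test = test_m$value[test_m$metric == "accuracy"],
    sensitivity_test = test_m$value[test_m$metric == "sensitivity"],
    specificity_test = test_m$value[test_m$metric == "specificity"],
    precision_test = test_m$value[test_m$metric == "precision"]
  )
}

#' @method tidy panel_pipeline
#' @export
tidy.panel_pipeline <- function(x, ...) {
  bind_rows(
    mutate(x$evaluation$train$metrics, set = "train"),
    mutate(x$evaluation$test$metrics, set = "test")
  ) |>
    bind_rows(tibble(
      metric = "auc", value = c(x$evaluation$train$auc, x$evaluation$test$auc),
      set = c("train", "test")
    )) |>
    select("set", "metric", "value")
}
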