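enum_setup <- function(seed = 1, n_probes = 8, n_informative = 2,
                       effect = 4, n_per_class = 15) {
  sim <- simulate_expression(n_cancer = n_per_class, n_normal = n_per_class,
    n_probes = n_probes, n_informative = n_informative, effect_size = effect,
    sample_effect_sd = 0.3, seed = seed)
  sp <- split_train_test(sim$expression, sim$labels, seed = seed + 1)
  c(sp, list(informative = sim$informative, probes = probe_ids(sim$expression)))
}

test_that("small candidate sets fall back to exhaustive enumeration", {
  d <- enum_setup(seed = 5)
  cand <- d$probes[1:4]
  rk <- enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
    cand, panel_size = 2, n_panels = 10, seed = 3)
  expect_equal(nrow(rk), choose(4, 2))
  expect_true(attr(rk, "exhaustive"))
  expect_true(all(is.finite(rk$auc_test)))
  # all panels distinct, each a 2-subset of the candidates
  keys <- vapply(rk$panel, paste, "", collapse = "|")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(vapply(rk$panel, function(p)
    length(p) == 2 && all(p %in% cand), logical(1))))
})

test_that("rankings are sorted, reproducible, and a permutation of the panels", {
  d <- enum_setup(seed = 6)
  rk1 <- enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
    d$probes, panel_size = 3, n_panels = 12, seed = 11)
  rk2 <- enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
    d$probes, panel_size = 3, n_panels = 12, seed = 11)
  expect_identical(rk1$panel, rk2$panel)
  expect_identical(rk1$auc_test, rk2$auc_test)
  expect_equal(nrow(rk1), 12)
  expect_true(all(diff(rk1$auc_test) <= 0))
  expect_setequal(rk1$panel_id, seq_len(12))

  # every reported AUC is reproduced from the stored decision scores
  yte <- d$test_labels$y[match(sample_ids(d$test), d$test_labels$sample_id)]
  recomputed <- vapply(rk1$scores, roc_auc, numeric(1), truth = yte)
  expect_equal(rk1$auc_test, recomputed)

  expect_error(
    enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
      d$probes[1:3], panel_size = 4, n_panels = 5, seed = 1),
    class = "panelselect_bad_panel_size")
})

test_that("the informative panel outranks pure-noise panels", {
  firsts <- withr::with_seed(23, {
    replicate(15, {
      d <- enum_setup(seed = sample.int(1e6, 1), n_probes = 6,
        n_informative = 2, effect = 5, n_per_class = 25)
      rk <- enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
        d$probes, panel_size = 2, n_panels = choose(6, 2), seed = 2)
      auc_of <- function(p) rk$auc_test[vapply(rk$panel, setequal, logical(1), p)]
      inf_auc <- auc_of(d$informative)
      pure_noise <- !vapply(rk$panel, function(p) any(p %in% d$informative),
        logical(1))
      # top of the ranking (modulo exact ties) and clear of every noise panel
      inf_auc >= max(rk$auc_test) - 1e-12 && all(inf_auc > rk$auc_test[pure_noise])
    })
  })
  expect_gte(mean(firsts), 0.8)
})

test_that("panel ROC comparison flags the designated panel and keeps the sort order", {
  d <- enum_setup(seed = 7, effect = 5)
  rk <- enumerate_panels(d$train, d$train_labels, d$test, d$test_labels,
    d$probes, panel_size = 2, n_panels = 8, seed = 4)
  panels <- list(best = rk$panel[[1]], worst = rk$panel[[nrow(rk)]],
    twin = rk$panel[[1]])
  rocs <- compare_panel_rocs(panels, d$train, d$train_labels, d$test,
    d$test_labels, flag = "best")
  aucs <- rocs |> dplyr::distinct(panel, auc)
  expect_gte(aucs$auc[aucs$panel == "best"], aucs$auc[aucs$panel == "worst"])
  # identical panels give identical curves
  expect_equal(
    rocs[rocs$panel == "best", c("fpr", "tpr")],
    rocs[rocs$panel == "twin", c("fpr", "tpr")],
    ignore_attr = TRUE)
  expect_true(all(rocs$flagged[rocs$panel == "best"]))
  p <- ggplot2::ggplot_build(autoplot(rocs))
  expect_s3_class(p$plot, "ggplot")
})
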