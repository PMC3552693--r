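test_that("per-probe F test matches closed form and stats::oneway.test", {
  res <- probe_group_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, -1, -1, -1))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$p_value,
    pf(13.5, 1, 4, lower.tail = FALSE))

  # random probes: agreement with the standard equal-variance ANOVA
  withr::with_seed(31, {
    for (rep in 1:5) {
      v <- rnorm(12)
      y <- rep(c(1, -1), times = c(5, 7))
      got <- probe_group_test(v, y)
      ref <- oneway.test(v ~ factor(y), var.equal = TRUE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, unname(ref$p.value))
    }
  })

  # identical group means with spread: no between-group evidence
  flat <- probe_group_test(c(1, 3, 2, 1, 3, 2), c(1, 1, 1, -1, -1, -1))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # zero within-class variance: flagged, p = 0, no exception
  expect_warning(
    deg <- probe_group_test(c(1, 1, 1, 2, 2, 2), c(1, 1, 1, -1, -1, -1)),
    "degenerate")
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
})

test_that("null p-values are uniform and type-I error is controlled", {
  n <- 20
  withr::with_seed(99, {
    v <- rnorm(n)
    p <- replicate(400, {
      y <- sample(rep(c(1, -1), each = n / 2))
      probe_group_test(v, y)$p_value
    })
  })
  # permutation p-values are discrete, so ties are expected; the KS check is
  # approximate
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  # fraction below alpha within binomial error of alpha
  alpha <- 0.1
  frac <- mean(p < alpha)
  expect_lt(abs(frac - alpha), 3 * sqrt(alpha * (1 - alpha) / length(p)) + 0.01)
})

test_that("BH step-up adjustment matches the hand-worked and reference values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "panelselect_bad_p")
  withr::with_seed(5, {
    p <- runif(200)^2
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
    expect_true(all(bh_adjust(p) >= p))
  })
})

test_that("Storey q-values reproduce the worked example and reduce to BH", {
  out <- storey_qvalue(c(0.01, 0.02, 0.03, 0.9), lambda = 0.5)
  expect_equal(out$pi0, 0.5)
  expect_equal(out$q, c(0.02, 0.02, 0.02, 0.45))

  # pi0 estimate clamps into (0, 1]
  expect_equal(storey_qvalue(rep(0.9, 10), lambda = 0.5)$pi0, 1)
  expect_equal(storey_qvalue(rep(0.01, 10), lambda = 0.5)$pi0, 1)
  expect_error(storey_qvalue(c(0.5), lambda = 1), class = "panelselect_bad_lambda")

  # uniform null: pi0 near 1
  withr::with_seed(8, p <- runif(10000))
  expect_lt(abs(storey_qvalue(p, 0.5)$pi0 - 1), 0.1)

  # with pi0 forced to 1 (all p above lambda impossible -> use lambda 0)
  withr::with_seed(9, p <- runif(50))
  expect_equal(storey_qvalue(p, lambda = 0)$q,
    pmin(sum(p > 0) / 50 * bh_adjust(p), 1))
})

test_that("marker selection applies a strict threshold and reports the FPR count", {
  tab <- tibble::tibble(
    probe_id = paste0("p", 1:6),
    statistic = 6:1,
    p_value = c(0.001, 0.002, 0.003, 0.2, 0.01, 0.5),
    q_value = c(0.005, 0.009, 0.01, 0.4, 0.02, 0.6)
  )
  sel <- select_markers(tab, 0.01)
  expect_equal(sel$probe_id, c("p1", "p2"))   # q == 0.01 excluded (strict <)
  expect_equal(attr(sel, "fpr"), 0.01 * 2)

  expect_equal(nrow(select_markers(tab, 0)), 0)
  expect_equal(attr(select_markers(tab, 0), "fpr"), 0)

  all_in <- dplyr::mutate(tab, q_value = 0.005)
  expect_equal(nrow(select_markers(all_in, 0.01)), 6)

  # invariant to probe-row ordering of the input
  shuffled <- tab[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(select_markers(shuffled, 0.01), sel, ignore_attr = TRUE)
})

test_that("screening a simulated cohort recovers informative probes at large effect", {
  hits <- withr::with_seed(17, {
    replicate(5, {
      seed <- sample.int(1e6, 1)
      sim <- simulate_expression(n_cancer = 30, n_normal = 30, n_probes = 300,
        n_informative = 10, effect_size = 5, seed = seed)
      tab <- screen_probes(sim$expression, sim$labels)
      sel <- select_markers(tab, 0.01)
      mean(sim$informative %in% sel$probe_id)
    })
  })
  expect_gte(mean(hits), 0.9)
})
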