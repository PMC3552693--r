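test_that("expression and label files parse, validate, and round-trip", {
  d <- make_expr(matrix(c(1.5, 2.25, 3, 4, 5.125, 6), nrow = 2),
    classes = c("cancer", "normal", "cancer"))
  ef <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_expression(d$expr, ef)
  write_labels(d$labels, lf)

  expr <- read_expression(ef, lf)
  expect_equal(dim(expr), c(2, 4))
  labs <- attr(expr, "labels")
  expect_setequal(labs$y, c(1, -1))
  expect_equal(labs$y[labs$sample_id == "s1"], 1)

  # lossless round trip, attributes aside
  attr(expr, "labels") <- NULL
  expect_equal(expr, d$expr)

  # each malformed input is a distinct reported failure
  writeLines(c("s1\tcancer", "s2\tnormal"), lf)          # s3 unlabelled
  expect_error(read_expression(ef, lf), class = "panelselect_missing_label")
  writeLines(c("s1\tcancer", "s2\tnormal", "s3\tcancer", "s9\tnormal"), lf)
  expect_error(read_expression(ef, lf), class = "panelselect_unknown_sample")
  writeLines(c("probe_id\ts1\ts2\ts3", "p1\t1\t2\tx", "p2\t1\t2\t3"), ef)
  expect_error(read_expression(ef), class = "panelselect_non_numeric")
  writeLines(c("probe_id\ts1\ts2\ts3", "p1\t1\t2\t3", "p1\t1\t2\t3"), ef)
  expect_error(read_expression(ef), class = "panelselect_duplicate_probe")
})

test_that("log2 transform maps values elementwise and rejects its domain edge", {
  d <- make_expr(matrix(c(4, 1, 8, 0.5, 2, 16), nrow = 2))
  out <- log2_transform(d$expr)
  expect_equal(expr_matrix(out), log2(expr_matrix(d$expr)))
  expect_equal(unname(expr_matrix(out)[1, 1]), 2)
  expect_equal(unname(expr_matrix(out)[2, 1]), 0)

  d0 <- make_expr(matrix(c(4, 1, 0, 2), nrow = 2))
  err <- expect_error(log2_transform(d0$expr), class = "panelselect_log2_domain")
  expect_match(conditionMessage(err), "p1")
  expect_match(conditionMessage(err), "s2")
})

test_that("median centering zeroes each probe's median and is idempotent", {
  vals <- rbind(c(1, 2, 3, 100), c(5, 5, 5, 5), c(1, 2, 3, 10))
  d <- make_expr(vals)
  out <- expr_matrix(median_center(d$expr))
  expect_equal(unname(out[1, 1:3]), c(-1.5, -0.5, 0.5))
  expect_equal(unname(out[2, ]), rep(0, 4))
  # even-length row: median is the mean of the middle two
  expect_equal(unname(out[3, ]), c(-1.5, -0.5, 0.5, 7.5))
  expect_true(all(apply(out, 1, median) == 0))
  expect_equal(median_center(median_center(d$expr)), median_center(d$expr))

  # per-sample mode centres columns instead
  bycol <- expr_matrix(median_center(d$expr, by = "sample"))
  expect_true(all(apply(bycol, 2, median) == 0))
})

test_that("stratified split matches the two-class cohort geometry", {
  sim <- simulate_expression(n_cancer = 67, n_normal = 63, n_probes = 5,
    n_informative = 0, seed = 11)
  sp <- split_train_test(sim$expression, sim$labels, train_fraction = 0.5,
    seed = 42)
  expect_equal(length(sample_ids(sp$train)), 65)
  expect_equal(length(sample_ids(sp$test)), 65)
  tr_cancer <- sum(sp$train_labels$class == "cancer")
  tr_normal <- sum(sp$train_labels$class == "normal")
  expect_lte(abs(tr_cancer - 33), 1)
  expect_lte(abs(tr_normal - 32), 1)
})

test_that("splitting partitions the samples deterministically for every seed", {
  sim <- simulate_expression(n_cancer = 9, n_normal = 7, n_probes = 4,
    n_informative = 0, seed = 2)
  all_ids <- sample_ids(sim$expression)
  for (seed in 1:10) {
    sp <- split_train_test(sim$expression, sim$labels, seed = seed)
    expect_setequal(c(sample_ids(sp$train), sample_ids(sp$test)), all_ids)
    expect_length(intersect(sample_ids(sp$train), sample_ids(sp$test)), 0)
  }
  a <- split_train_test(sim$expression, sim$labels, seed = 7)
  b <- split_train_test(sim$expression, sim$labels, seed = 7)
  expect_identical(a$assignment, b$assignment)

  # 2+2 samples at fraction 0.5: exact per-class stratification
  d <- make_expr(matrix(rnorm(8), nrow = 2),
    classes = c("cancer", "cancer", "normal", "normal"))
  sp <- split_train_test(d$expr, d$labels, train_fraction = 0.5, seed = 1)
  expect_equal(sort(table(sp$train_labels$class)), sort(c(cancer = 1L, normal = 1L)),
    ignore_attr = TRUE)

  # a fraction leaving a class empty is an error
  d2 <- make_expr(matrix(rnorm(8), nrow = 1),
    classes = c("cancer", rep("normal", 7)))
  expect_error(
    split_train_test(d2$expr, d2$labels, train_fraction = 0.9, seed = 1,
      stratified = FALSE),
    class = "panelselect_degenerate_split")
})
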