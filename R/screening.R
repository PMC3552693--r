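#' One-way ANOVA group test for a single probe
#'
#' Tests the fixed group (class) effect for one probe's expression values
#' with a one-way fixed-effect ANOVA: F = MSB/MSW on (1, n - 2) degrees of
#' freedom. With one observation per sample the per-sample random effect is
#' confounded with the residual, so the two-class mixed model reduces to
#' exactly this test.
#'
#' Degenerate inputs are flagged rather than raised: zero pooled
#' within-class variance with distinct group means gives `p_value = 0`
#' (infinite F); a constant probe gives `statistic = 0`, `p_value = 1`.
#'
#' @param values Numeric vector, one expression value per sample.
#' @param y Class vector in \{-1, +1\} (or a label tibble's `y` column).
#' @return A one-row tibble with `statistic`, `p_value`, and `degenerate`.
#' @export
probe_group_test <- function(values, y) {
  stopifnot(length(values) == length(y), all(y %in% c(-1, 1)))
  if (sum(y == 1) < 2 || sum(y == -1) < 2) {
    abort("need at least two samples per class", class = "panelselect_too_few")
  }
  res <- f_test_rows(matrix(values, nrow = 1), y)
  if (any(res$degenerate)) {
    warn("degenerate probe: zero within-class or total variance")
  }
  tibble(statistic = res$statistic, p_value = res$p_value,
    degenerate = res$degenerate)
}

# Vectorized per-row one-way two-group ANOVA (closed form).
# X: probes x samples, y in {-1, +1}.
f_test_rows <- function(X, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == -1)
  n <- n1 + n0
  m1 <- rowMeans(X[, y == 1, drop = FALSE])
  m0 <- rowMeans(X[, y == -1, drop = FALSE])
  g <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - g)^2 + n0 * (m0 - g)^2
  sst <- rowSums((X - g)^2)
  ssw <- pmax(sst - ssb, 0)
  msw <- ssw / (n - 2)
  f <- ssb / msw
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  degenerate <- msw <= 0
  # zero spread within groups: perfectly separated (p = 0) unless the probe
  # is constant, in which case there is no evidence at all (F = 0, p = 1)
  f[degenerate & ssb > 0] <- Inf
  p[degenerate & ssb > 0] <- 0
  f[degenerate & ssb <= 0] <- 0
  p[degenerate & ssb <= 0] <- 1
  list(statistic = unname(f), p_value = unname(p), degenerate = unname(degenerate))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: p-values are ordered, multiplied by m/rank, a
#' running minimum is taken from the largest rank down, and values are capped
#' at 1. Output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, each >= its raw p-value.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    abort("p-values must lie in [0, 1]", class = "panelselect_bad_p")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m * (1 - lambda))`, clamped to (0, 1\] (when no
#' p-value exceeds `lambda` the estimate is undefined and pi0 is set to 1,
#' the conservative choice), and returns `q = pi0 *` the BH step-up value,
#' capped at 1. With `pi0 = 1` the q-values equal [bh_adjust()] exactly.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning parameter in \[0, 1) for the pi0 estimate.
#' @return A list with `q` (numeric vector) and `pi0` (scalar).
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  if (length(lambda) != 1 || lambda < 0 || lambda >= 1) {
    abort("lambda must be a single value in [0, 1)", class = "panelselect_bad_lambda")
  }
  if (any(p < 0 | p > 1 | is.na(p))) {
    abort("p-values must lie in [0, 1]", class = "panelselect_bad_p")
  }
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  if (pi0 <= 0) pi0 <- 1
  pi0 <- min(pi0, 1)
  q <- pmin(pi0 * bh_adjust(p), 1)
  list(q = q, pi0 = pi0)
}

#' Per-probe differential-expression screening
#'
#' Runs the per-probe one-way ANOVA group test across an expression matrix
#' and attaches Benjamini-Hochberg adjusted p-values and Storey-Tibshirani
#' q-values. This is the screening stage applied to the training set only.
#'
#' @param expr Expression tibble (probes x samples).
#' @param labels Label tibble covering the samples of `expr`.
#' @param lambda Storey pi0 tuning parameter, see [storey_qvalue()].
#' @return A tibble with one row per probe in input order: `probe_id`,
#'   `statistic`, `p_value`, `p_bh`, `q_value`, `degenerate`; the pi0
#'   estimate and lambda are attached as attributes `pi0` and `lambda`.
#' @export
screen_probes <- function(expr, labels, lambda = 0.5) {
  validate_expression(expr, labels)
  X <- expr_matrix(expr)
  y <- labels$y[match(colnames(X), labels$sample_id)]
  if (sum(y == 1) < 2 || sum(y == -1) < 2) {
    abort("need at least two samples per class", class = "panelselect_too_few")
  }
  ft <- f_test_rows(X, y)
  if (any(ft$degenerate)) {
    warn(sprintf("%d probe(s) with zero within-class or total variance",
      sum(ft$degenerate)))
  }
  sq <- storey_qvalue(ft$p_value, lambda = lambda)
  out <- tibble(
    probe_id = expr$probe_id,
    statistic = ft$statistic,
    p_value = ft$p_value,
    p_bh = bh_adjust(ft$p_value),
    q_value = sq$q,
    degenerate = ft$degenerate
  )
  attr(out, "pi0") <- sq$pi0
  attr(out, "lambda") <- lambda
  out
}

#' Select markers below a q-value threshold
#'
#' Keeps probes with `q_value` strictly below `q_threshold` (the strict
#' inequality matters at ties), ordered by ascending q then probe ID. The
#' expected number of false positives among the declared changes,
#' `q_threshold * number selected`, is attached as attribute `fpr` — note
#' this is an expected count, not a rate.
#'
#' @param screen_tab Screening tibble from [screen_probes()].
#' @param q_threshold Significance threshold on the q-value (default 0.01).
#' @return The selected rows, arranged by `q_value` then `probe_id`, with
#'   attributes `q_threshold` and `fpr`.
#' @export
select_markers <- function(screen_tab, q_threshold = 0.01) {
  stopifnot(is.data.frame(screen_tab),
    all(c("probe_id", "q_value") %in% names(screen_tab)))
  out <- screen_tab |>
    filter(.data$q_value < q_threshold) |>
    arrange(.data$q_value, .data$probe_id)
  attr(out, "q_threshold") <- q_threshold
  attr(out, "fpr") <- q_threshold * nrow(out)
  out
}
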