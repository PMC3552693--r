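#' Simulate a two-class expression matrix
#'
#' Generates log-ratio-scale expression values with the additive structure
#' the screening model assumes:
#' `value(p, j) = mu_p + T(p, class_j) + S_j + eps_pj`, where `mu_p` is a
#' per-probe baseline, `S_j ~ N(0, sample_effect_sd^2)` is a random effect
#' shared by every probe of sample j (inducing inter-probe correlation),
#' and `eps ~ N(0, residual_sd^2)`. Informative probes carry a class mean
#' shift of `effect_size * residual_sd`, split as +/- half per class with a
#' random sign per probe so both up- and down-regulated markers occur;
#' non-informative probes have `T = 0`.
#'
#' Defaults mirror the geometry of a 130-sample peripheral-blood cohort
#' (67 cancer / 63 normal) with 2000 probes of which 42 are informative;
#' the default effect size (1.75 residual sd) is the weakest at which a
#' q < 0.01 screen of a 65-sample training half typically recovers the
#' full 42-marker set.
#'
#' @param n_cancer,n_normal Samples per class.
#' @param n_probes Total probes.
#' @param n_informative Number of informative probes (<= `n_probes`).
#' @param effect_size Class mean shift in units of `residual_sd`.
#' @param sample_effect_sd Standard deviation of the shared per-sample
#'   random effect (>= 0).
#' @param residual_sd Residual standard deviation (> 0).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A list: `expression` (probe-by-sample tibble), `labels` (label
#'   tibble), `informative` (character vector of informative probe IDs),
#'   and `spec` (the parameters used).
#' @export
simulate_expression <- function(n_cancer = 67, n_normal = 63, n_probes = 2000,
                                n_informative = 42, effect_size = 1.75,
                                sample_effect_sd = 0.5, residual_sd = 1,
                                seed = 1) {
  stopifnot(n_cancer >= 1, n_normal >= 1, n_probes >= 1,
    n_informative >= 0, n_informative <= n_probes,
    sample_effect_sd >= 0, residual_sd > 0)
  n <- n_cancer + n_normal
  probe_id <- sprintf("probe_%0*d", nchar(n_probes), seq_len(n_probes))
  sample_id <- sprintf("s%0*d", nchar(n), seq_len(n))
  cls <- c(rep("cancer", n_cancer), rep("normal", n_normal))
  ysign <- ifelse(cls == "cancer", 1, -1)
  vals <- withr::with_seed(seed, {
    mu <- rnorm(n_probes, 0, 1)
    informative_idx <- sort(sample.int(n_probes, n_informative))
    dir <- sample(c(-1, 1), n_informative, replace = TRUE)
    S <- rnorm(n, 0, sample_effect_sd)
    eps <- matrix(rnorm(n_probes * n, 0, residual_sd), n_probes, n)
    T_shift <- matrix(0, n_probes, n)
    if (n_informative > 0) {
      half <- effect_size * residual_sd / 2
      T_shift[informative_idx, ] <- outer(dir * half, ysign)
    }
    list(m = mu + T_shift + matrix(S, n_probes, n, byrow = TRUE) + eps,
      informative = probe_id[informative_idx])
  })
  m <- vals$m
  dimnames(m) <- list(probe_id, sample_id)
  labels <- as_labels(tibble(sample_id = sample_id, class = cls))
  list(
    expression = new_expr(m, probe_id),
    labels = labels,
    informative = vals$informative,
    spec = list(n_cancer = n_cancer, n_normal = n_normal, n_probes = n_probes,
      n_informative = n_informative, effect_size = effect_size,
      sample_effect_sd = sample_effect_sd, residual_sd = residual_sd,
      seed = seed)
  )
}

fixture_specs <- list(
  tiny = list(n_cancer = 4, n_normal = 4, n_probes = 6, n_informative = 2,
    effect_size = 3, sample_effect_sd = 0.5, residual_sd = 1, seed = 101),
  null = list(n_cancer = 15, n_normal = 15, n_probes = 100, n_informative = 0,
    effect_size = 0, sample_effect_sd = 0.5, residual_sd = 1, seed = 102),
  paper_shaped = list(n_cancer = 67, n_normal = 63, n_probes = 2000,
    n_informative = 42, effect_size = 1.75, sample_effect_sd = 0.5,
    residual_sd = 1, seed = 103)
)

#' Write a named synthetic fixture to disk
#'
#' Materialises one of three canned simulation scenarios as plain-text
#' files: `tiny` (8 samples x 6 probes, for oracle-scale tests), `null`
#' (30 samples x 100 probes, no informative probe), and `paper_shaped`
#' (130 samples, 67 cancer / 63 normal, 2000 probes, 42 informative).
#' Regeneration with the same name is byte-identical.
#'
#' @param name One of `"tiny"`, `"null"`, `"paper_shaped"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths (`expression`, `labels`,
#'   `truth`) plus the simulation itself (`sim`).
#' @export
make_fixture <- function(name = c("tiny", "null", "paper_shaped"),
                         dir = tempfile("fixture_")) {
  name <- match.arg(name)
  spec <- fixture_specs[[name]]
  sim <- do.call(simulate_expression, spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, paste0(name, "_expression.tsv")),
    labels = file.path(dir, paste0(name, "_labels.tsv")),
    truth = file.path(dir, paste0(name, "_informative.txt"))
  )
  write_expression(sim$expression, paths$expression)
  write_labels(sim$labels, paths$labels)
  writeLines(sim$informative, paths$truth)
  invisible(c(paths, list(sim = sim)))
}
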