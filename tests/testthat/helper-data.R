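# Small builders shared across tests; everything is generated in code.

# samples-by-features matrix with two informative features and noise,
# classes balanced, deterministic given seed
make_xy <- function(n = 40, n_features = 5, n_informative = 2,
                    effect = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, -1), length.out = n)
    X <- matrix(rnorm(n * n_features), n, n_features)
    colnames(X) <- paste0("f", seq_len(n_features))
    for (j in seq_len(n_informative)) {
      X[, j] <- X[, j] + y * effect / 2
    }
    list(X = X, y = y, informative = colnames(X)[seq_len(n_informative)])
  })
}

# tiny expression tibble + labels written from an explicit matrix
make_expr <- function(values, probe_id = NULL, sample_id = NULL,
                      classes = NULL) {
  if (is.null(probe_id)) probe_id <- paste0("p", seq_len(nrow(values)))
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(probe_id, sample_id)
  expr <- dplyr::bind_cols(
    tibble::tibble(probe_id = probe_id),
    tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  )
  labels <- if (!is.null(classes)) {
    as_labels(tibble::tibble(sample_id = sample_id, class = classes))
  }
  list(expr = expr, labels = labels)
}

# brute-force AUC: concordant-pair count with half credit for ties
pair_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# brute-force LOOCV of a fixed feature panel, written directly against
# e1071 (independent of loocv_pass); the held-out model is the RBF SVM
# with width 1 / (n_features * var(X)), matching the evaluation convention
brute_loocv_error <- function(X, y, panel, C = 1) {
  X <- X[, panel, drop = FALSE]
  errs <- 0L
  for (i in seq_len(nrow(X))) {
    Xtr <- X[-i, , drop = FALSE]
    fit <- e1071::svm(x = Xtr, y = factor(y[-i], levels = c(-1, 1)),
      kernel = "radial", cost = C,
      gamma = 1 / (ncol(Xtr) * var(as.vector(Xtr))), scale = FALSE)
    pred <- as.numeric(as.character(predict(fit, X[i, , drop = FALSE])))
    errs <- errs + as.integer(pred != y[i])
  }
  errs
}
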