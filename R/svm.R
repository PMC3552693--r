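#' SVM configuration
#'
#' Bundles the soft-margin SVM hyperparameters used across the pipeline.
#' `kernel` is the kernel of the final reported classifier; `rank_kernel`
#' controls how per-feature ranking weights are produced inside the
#' recursive-elimination loop: `"linear"` fits a linear-kernel SVM on the
#' current feature subset (same `C`) and ranks by its primal weights |W|,
#' `"rbf-margin"` trains the RBF model per fold and ranks by the
#' kernel-space margin change from dropping each feature.
#'
#' @param kernel Kernel of the final classifier: `"rbf"` (Gaussian radial
#'   basis function, the default) or `"linear"`.
#' @param C Soft-margin cost parameter, > 0 (default 1).
#' @param gamma RBF kernel width; default `NULL` means
#'   `1 / (n_features * var(X))`, computed at fit time.
#' @param rank_kernel Ranking-weight source for feature elimination.
#' @return A list of class `svm_control`.
#' @export
svm_control <- function(kernel = c("rbf", "linear"), C = 1, gamma = NULL,
                        rank_kernel = c("linear", "rbf-margin")) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0)
  structure(
    list(kernel = match.arg(kernel), C = C, gamma = gamma,
      rank_kernel = match.arg(rank_kernel)),
    class = "svm_control"
  )
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X))
  mode(X) <- "numeric"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

default_gamma <- function(X) {
  v <- var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train a two-class soft-margin SVM
#'
#' Fits a support vector machine on a samples-by-features matrix with class
#' labels in \{-1, +1\} (+1 = cancer). Training is deterministic given the
#' data and hyperparameters; features are used unscaled. Decision scores are
#' oriented so that a positive score predicts the +1 class.
#'
#' @param X Numeric samples-by-features matrix (or data frame); column names
#'   are the feature IDs.
#' @param y Class vector in \{-1, +1\}, one per row of `X`.
#' @param control An [svm_control()] object; its `kernel`, `C`, and `gamma`
#'   are used.
#' @param kernel Optional override of `control$kernel`.
#' @return An object of class `svm_fit` holding the fitted model, the
#'   hyperparameters actually used, the training feature IDs, and (for the
#'   linear kernel) the primal weight vector `w` and bias `b`.
#' @export
svm_train <- function(X, y, control = svm_control(), kernel = NULL) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (!all(y %in% c(-1, 1))) {
    abort("labels must be -1 or +1", class = "panelselect_bad_y")
  }
  if (length(unique(y)) < 2) {
    abort("both classes must be present in y", class = "panelselect_one_class")
  }
  if (!all(is.finite(X))) {
    abort("feature matrix must be finite", class = "panelselect_non_finite")
  }
  kernel <- kernel %||% control$kernel
  gamma <- control$gamma %||% default_gamma(X)
  model <- e1071::svm(
    x = X, y = factor(y, levels = c(-1, 1)),
    kernel = switch(kernel, rbf = "radial", linear = "linear"),
    cost = control$C, gamma = gamma, scale = FALSE
  )
  # libsvm orients decision values toward whichever class it saw first;
  # recover the orientation from the decision-value column name
  dv <- attr(predict(model, X[1, , drop = FALSE], decision.values = TRUE),
    "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  flip <- if (first == "1") 1 else -1
  fit <- structure(
    list(model = model, kernel = kernel, C = control$C, gamma = gamma,
      flip = flip, feature_ids = colnames(X)),
    class = "svm_fit"
  )
  if (kernel == "linear") {
    fit$w <- drop(flip * crossprod(model$coefs, model$SV))
    names(fit$w) <- colnames(X)
    fit$b <- flip * -model$rho
  }
  fit
}

check_features <- function(fit, X) {
  X <- as_feature_matrix(X)
  if (!setequal(colnames(X), fit$feature_ids) ||
      ncol(X) != length(fit$feature_ids)) {
    abort("feature columns do not match the model's training features",
      class = "panelselect_feature_mismatch")
  }
  X[, fit$feature_ids, drop = FALSE]
}

#' Signed decision scores
#'
#' Evaluates the fitted decision function on new samples. Scores are signed
#' distances in kernel space: positive predicts the +1 (cancer) class, and
#' `sign(score)` always agrees with [predict.svm_fit()].
#'
#' @param fit An `svm_fit` object.
#' @param X Samples-by-features matrix with the model's training features.
#' @return Numeric vector of decision scores, one per row of `X`.
#' @export
decision_scores <- function(fit, X) {
  X <- check_features(fit, X)
  if (nrow(X) == 0) return(numeric(0))
  dv <- attr(predict(fit$model, X, decision.values = TRUE), "decision.values")
  unname(fit$flip * dv[, 1])
}

#' Predict classes from a fitted SVM
#'
#' @param object An `svm_fit` object.
#' @param newdata Samples-by-features matrix.
#' @param ... Unused.
#' @return Numeric vector in \{-1, +1\}; a score of exactly zero maps to +1.
#' @export
predict.svm_fit <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  ifelse(s >= 0, 1, -1)
}

#' Per-feature ranking weights
#'
#' Returns the signed primal weight vector `W` used as the elimination
#' ranking signal (callers take `|W|`). For a linear-kernel model this is
#' the exact primal reconstruction `W = sum_i alpha_i y_i x_i`. For an RBF
#' model no primal weight exists, so an auxiliary linear-kernel SVM with the
#' same `C` is fitted to the same `(X, y)` and its weights are returned.
#'
#' @param fit An `svm_fit` object trained on `(X, y)`.
#' @param X,y The training data the model was fitted on (required for the
#'   RBF auxiliary fit; validated against the model's features).
#' @return Named numeric vector of signed weights, one per feature.
#' @export
svm_weights <- function(fit, X = NULL, y = NULL) {
  if (fit$kernel == "linear") return(fit$w)
  if (is.null(X) || is.null(y)) {
    abort("RBF weight extraction needs the training (X, y)",
      class = "panelselect_need_data")
  }
  X <- check_features(fit, X)
  aux <- svm_train(X, y, control = svm_control(kernel = "linear", C = fit$C))
  aux$w
}

# Guyon-style kernel ranking criterion for an RBF fit: the change in the
# margin objective J = (1/2) a' K a from removing each feature, computed
# over the support vectors (alphas held fixed).
rbf_margin_criterion <- function(fit, X) {
  X <- check_features(fit, X)
  S <- fit$model$SV
  a <- drop(fit$model$coefs)
  g <- fit$gamma
  sq <- rowSums(S^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(S)
  K <- exp(-g * pmax(D, 0))
  base <- drop(crossprod(a, K %*% a))
  vapply(seq_len(ncol(S)), function(f) {
    d_f <- outer(S[, f], S[, f], "-")^2
    K_f <- exp(-g * pmax(D - d_f, 0))
    0.5 * (base - drop(crossprod(a, K_f %*% a)))
  }, numeric(1)) |> stats::setNames(colnames(S))
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit> kernel=%s C=%g gamma=%g features=%d support=%d\n",
    x$kernel, x$C, x$gamma, length(x$feature_ids), nrow(x$model$SV)))
  invisible(x)
}

#' @method glance svm_fit
#' @export
glance.svm_fit <- function(x, ...) {
  tibble(kernel = x$kernel, C = x$C, gamma = x$gamma,
    n_features = length(x$feature_ids), n_support = nrow(x$model$SV))
}

#' @method tidy svm_fit
#' @export
tidy.svm_fit <- function(x, X = NULL, y = NULL, ...) {
  w <- svm_weights(x, X, y)
  tibble(feature_id = names(w), weight = unname(w), abs_weight = abs(unname(w)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
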