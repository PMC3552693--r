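#' Read a probe-by-sample expression matrix
#'
#' Reads a delimited text file whose first column holds probe identifiers and
#' whose remaining columns hold one numeric expression value per sample. The
#' header row carries the sample identifiers. Files ending in `.csv` are read
#' as comma-separated; anything else as tab-separated.
#'
#' @param path Path to the expression matrix file.
#' @param label_path Optional path to a two-column sample label file
#'   (see [read_labels()]). When supplied, every sample in the matrix must
#'   have a label and every labelled sample must exist in the matrix; the
#'   label table is attached as the `"labels"` attribute.
#' @return A tibble with a character `probe_id` column followed by one numeric
#'   column per sample, rows and columns in file order.
#' @seealso [write_expression()], [read_labels()]
#' @export
read_expression <- function(path, label_path = NULL) {
  raw <- readr::read_delim(
    path,
    delim = expr_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2) {
    abort("expression file needs a probe_id column plus at least one sample column",
      class = "panelselect_parse_error")
  }
  names(raw)[1] <- "probe_id"
  dup <- raw$probe_id[duplicated(raw$probe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate probe ID(s): ", paste(unique(dup), collapse = ", ")),
      class = "panelselect_duplicate_probe")
  }
  for (col in names(raw)[-1]) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) & !is.na(txt) & txt != "NA")
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at probe '%s', sample '%s': '%s'",
        raw$probe_id[bad[1]], col, txt[bad[1]]),
        class = "panelselect_non_numeric")
    }
    raw[[col]] <- num
  }
  expr <- as_tibble(raw)
  if (!is.null(label_path)) {
    labels <- read_labels(label_path)
    validate_expression(expr, labels)
    attr(expr, "labels") <- labels
  }
  expr
}

expr_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read sample class labels
#'
#' Reads a two-column delimited file mapping sample ID to class. Classes are
#' matched case-insensitively against `cancer` and `normal` and encoded as
#' `y = +1` (cancer) and `y = -1` (normal). A header line
#' (`sample_id`, `class`) is tolerated and skipped.
#'
#' @param path Path to the label file.
#' @return A tibble with columns `sample_id`, `class` (lower-case), and `y`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_delim(
    path,
    delim = expr_delim(path),
    col_names = c("sample_id", "class"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(tab) > 0 && tolower(tab$class[1]) %in% c("class", "label", "group")) {
    tab <- tab[-1, , drop = FALSE]
  }
  as_labels(tab)
}

#' Build a label table from sample IDs and classes
#'
#' @param x A data frame with columns `sample_id` and `class`, or a character
#'   vector of classes named by sample ID.
#' @return A tibble with columns `sample_id`, `class`, and `y` in \{-1, +1\}.
#' @export
as_labels <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(sample_id = names(x), class = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("sample_id", "class") %in% names(x)))
  cls <- tolower(as.character(x$class))
  bad <- setdiff(unique(cls), c("cancer", "normal"))
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", "),
      " (expected 'cancer' or 'normal')"),
      class = "panelselect_bad_class")
  }
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sample ID(s) in labels: ",
      paste(unique(dup), collapse = ", ")),
      class = "panelselect_duplicate_sample")
  }
  tibble(
    sample_id = as.character(x$sample_id),
    class = cls,
    y = ifelse(cls == "cancer", 1L, -1L)
  )
}

#' Validate an expression matrix against its labels
#'
#' Checks the joint invariants: unique probe and sample IDs, all-finite
#' values, every sample labelled, no label for an unknown sample, and both
#' classes present.
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @param labels Label tibble as returned by [read_labels()]; optional.
#' @return `expr`, invisibly.
#' @export
validate_expression <- function(expr, labels = NULL) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "probe_id")
  samples <- sample_ids(expr)
  if (anyDuplicated(expr$probe_id)) {
    abort("duplicate probe IDs", class = "panelselect_duplicate_probe")
  }
  if (anyDuplicated(samples)) {
    abort("duplicate sample IDs", class = "panelselect_duplicate_sample")
  }
  vals <- expr_matrix(expr)
  if (!all(is.finite(vals))) {
    abort("expression values must be finite", class = "panelselect_non_finite")
  }
  if (!is.null(labels)) {
    unknown <- setdiff(labels$sample_id, samples)
    if (length(unknown) > 0) {
      abort(paste0("label file refers to unknown sample(s): ",
        paste(unknown, collapse = ", ")),
        class = "panelselect_unknown_sample")
    }
    missing <- setdiff(samples, labels$sample_id)
    if (length(missing) > 0) {
      abort(paste0("sample(s) missing a label: ",
        paste(missing, collapse = ", ")),
        class = "panelselect_missing_label")
    }
    if (length(unique(labels$y[labels$sample_id %in% samples])) < 2) {
      abort("both classes must be present", class = "panelselect_one_class")
    }
  }
  invisible(expr)
}

#' Write an expression matrix or label table
#'
#' Inverse of [read_expression()] / [read_labels()]; the written file
#' round-trips to an identical tibble (numeric values at full stored
#' precision). Delimiter follows the file extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_delim(expr, path, delim = expr_delim(path), progress = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param labels Label tibble with `sample_id` and `class` columns.
#' @export
write_labels <- function(labels, path) {
  readr::write_delim(labels[, c("sample_id", "class")], path,
    delim = expr_delim(path), col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Accessors for expression tibbles
#'
#' `sample_ids()` and `probe_ids()` return identifier vectors;
#' `expr_matrix()` returns the numeric probes-by-samples matrix with probe
#' IDs as row names.
#'
#' @param expr Expression tibble.
#' @return Character vector or numeric matrix.
#' @export
sample_ids <- function(expr) setdiff(names(expr), "probe_id")

#' @rdname sample_ids
#' @export
probe_ids <- function(expr) expr$probe_id

#' @rdname sample_ids
#' @export
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, sample_ids(expr), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- expr$probe_id
  m
}

new_expr <- function(values, probe_id) {
  out <- as_tibble(as.data.frame(values, check.names = FALSE))
  dplyr::bind_cols(tibble(probe_id = probe_id), out)
}

#' Log-ratio base-2 transformation
#'
#' Replaces every expression value by its base-2 logarithm. Intended for
#' data on the raw ratio scale; matrices already on the log scale must skip
#' this step (it is never applied implicitly by the pipeline).
#'
#' @param expr Expression tibble with strictly positive values.
#' @return Expression tibble of the same shape, values log2-transformed.
#' @export
log2_transform <- function(expr) {
  m <- expr_matrix(expr)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-positive value at probe '%s', sample '%s'; log2 undefined",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
      class = "panelselect_log2_domain")
  }
  new_expr(log2(m), expr$probe_id)
}

#' Median centering
#'
#' With `by = "probe"` (the default) the median of each probe's values across
#' all samples is subtracted from that probe, so every output row has median
#' zero; with `by = "sample"` each sample column is centred instead. The
#' operation is idempotent.
#'
#' @param expr Expression tibble on the log scale.
#' @param by Centre each `"probe"` row or each `"sample"` column.
#' @return Expression tibble of the same shape.
#' @export
median_center <- function(expr, by = c("probe", "sample")) {
  by <- match.arg(by)
  m <- expr_matrix(expr)
  if (by == "probe") {
    med <- apply(m, 1, median)
    m <- m - med
  } else {
    med <- apply(m, 2, median)
    m <- sweep(m, 2, med)
  }
  new_expr(m, expr$probe_id)
}

#' Stratified random train/test split
#'
#' Randomly partitions the samples into a training and a testing set.
#' With `stratified = TRUE` (the default) sampling is done within each class.
#' The training set receives `ceiling(train_fraction * n)` samples in total
#' (any fractional remainder favours training), allocated across classes by
#' largest remainder so each class's training count differs from
#' `train_fraction * class size` by less than 1; remainder ties go to the
#' class whose name sorts first. The split is deterministic given `seed` and
#' leaves the caller's RNG state untouched.
#'
#' @param expr Expression tibble.
#' @param labels Label tibble covering all samples of `expr`.
#' @param train_fraction Fraction of samples assigned to the training set,
#'   in (0, 1).
#' @param seed Integer seed controlling the random assignment.
#' @param stratified Sample within each class (default) or over all samples.
#' @return A list with elements `train`, `test` (expression tibbles),
#'   `train_labels`, `test_labels` (label tibbles), and `assignment`
#'   (tibble of `sample_id`, `class`, `set`).
#' @export
split_train_test <- function(expr, labels, train_fraction = 0.5, seed = 1,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  validate_expression(expr, labels)
  samples <- sample_ids(expr)
  labels <- labels[match(samples, labels$sample_id), ]
  n_train_total <- ceiling(train_fraction * length(samples))
  train_ids <- withr::with_seed(seed, {
    if (stratified) {
      by_class <- split(labels$sample_id, labels$class)
      exact <- train_fraction * lengths(by_class)
      n_tr <- floor(exact)
      short <- n_train_total - sum(n_tr)
      if (short > 0) {
        extra <- order(exact - n_tr, decreasing = TRUE)[seq_len(short)]
        n_tr[extra] <- n_tr[extra] + 1
      }
      unlist(Map(function(ids, k) sample(ids)[seq_len(k)], by_class, n_tr),
        use.names = FALSE)
    } else {
      sample(samples)[seq_len(n_train_total)]
    }
  })
  test_ids <- setdiff(samples, train_ids)
  for (ids in list(train_ids, test_ids)) {
    cls <- labels$class[labels$sample_id %in% ids]
    if (length(unique(cls)) < 2) {
      abort("train_fraction leaves a split without both classes",
        class = "panelselect_degenerate_split")
    }
  }
  subset_expr <- function(ids) expr[, c("probe_id", samples[samples %in% ids])]
  list(
    train = subset_expr(train_ids),
    test = subset_expr(test_ids),
    train_labels = labels[labels$sample_id %in% train_ids, ],
    test_labels = labels[labels$sample_id %in% test_ids, ],
    assignment = mutate(labels,
      set = ifelse(.data$sample_id %in% train_ids, "train", "test"))
  )
}
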