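# Labeled descriptor tables and the seeded train/test split.

#' Construct a labeled descriptor dataset
#'
#' The central container of the package: an n x d matrix of finite numeric
#' molecular descriptors plus a binary "active binding" label per row
#' (1 = known ligands bind the conformation, 0 = they do not).
#'
#' @param features Numeric matrix (or data frame coercible to one), n x d,
#'   all values finite.
#' @param labels Vector of 0/1 labels, length n.
#' @param feature_names Optional character vector of d descriptor names;
#'   defaults to the column names of `features` or `pro_f01`, `pro_f02`, ...
#' @param sample_ids Optional vector of n row identifiers; defaults to the
#'   0-based row index.
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels`, `feature_names`, `sample_ids`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL,
                            sample_ids = NULL) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("`features` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(features)
  d <- ncol(features)
  if (n == 0L || d == 0L) {
    stop("empty dataset: features must have at least one row and one column",
         call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("non-finite descriptor value (NaN/Inf/NA) in features", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("length of `labels` must equal nrow(features)", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must take only values 0 and 1", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- sprintf("pro_f%02d", seq_len(d))
    }
  }
  if (length(feature_names) != d) {
    stop("length of `feature_names` must equal ncol(features)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- seq_len(n) - 1L
  if (length(sample_ids) != n) {
    stop("length of `sample_ids` must equal nrow(features)", call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = as.character(feature_names), sample_ids = sample_ids),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0L, 1L)))
  cat(sprintf(
    "<labeled_dataset> %d samples x %d descriptors (class 0: %d, class 1: %d)\n",
    nrow(x$features), ncol(x$features), tab[["0"]], tab[["1"]]))
  invisible(x)
}

#' Number of samples per class
#'
#' @param data A [labeled_dataset()].
#' @return Named integer vector with elements `"0"` and `"1"`.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  c("0" = sum(data$labels == 0L), "1" = sum(data$labels == 1L))
}

#' Read a labeled descriptor table from CSV
#'
#' Expects a comma-separated file with a header row, '.' decimal separator,
#' one numeric column per descriptor and one 0/1 label column. An optional
#' id column may be named via `id_column`; otherwise ids default to the
#' 0-based row index.
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the label column (default `"active_binding"`).
#' @param id_column Optional name of a sample-id column.
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(path, label_column = "active_binding",
                         id_column = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: no data rows", call. = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not found", id_column), call. = FALSE)
    }
    ids <- df[[id_column]]
    df[[id_column]] <- NULL
  }
  raw_labels <- df[[label_column]]
  df[[label_column]] <- NULL
  lab_num <- suppressWarnings(as.numeric(raw_labels))
  if (anyNA(lab_num) || !all(lab_num %in% c(0, 1))) {
    stop("labels must take only values 0 and 1", call. = FALSE)
  }
  if (ncol(df) == 0L) stop("empty table: no descriptor columns", call. = FALSE)
  num_ok <- vapply(df, is.numeric, logical(1))
  if (!all(num_ok)) {
    stop(sprintf("non-numeric descriptor column(s): %s",
                 paste(names(df)[!num_ok], collapse = ", ")), call. = FALSE)
  }
  feats <- as.matrix(df)
  labeled_dataset(feats, as.integer(lab_num),
                  feature_names = names(df), sample_ids = ids)
}

#' Write a labeled descriptor table to CSV
#'
#' Deterministic column order: `sample_id`, descriptors in stored order,
#' label column last, plus an optional provenance column (used to flag
#' SMOTE-synthesized rows).
#'
#' @param data A [labeled_dataset()].
#' @param path Output file path.
#' @param label_column Name for the label column.
#' @param provenance Optional character vector (e.g. `"original"`/`"smote"`)
#'   of length n written as a final `provenance` column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, label_column = "active_binding",
                          provenance = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- data.frame(sample_id = data$sample_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$features, check.names = FALSE))
  df[[label_column]] <- data$labels
  if (!is.null(provenance)) {
    stopifnot(length(provenance) == nrow(data$features))
    df[["provenance"]] <- provenance
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Subset a labeled_dataset by row indices, preserving ids.
subset_rows <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  feature_names = data$feature_names,
                  sample_ids = data$sample_ids[idx])
}

#' Seeded random train/test split
#'
#' Draws `floor(fraction * n)` training rows uniformly at random without
#' replacement and without stratification; the remaining rows form the test
#' set. Stratified sampling (preserving the class ratio exactly) is available
#' behind `stratify = TRUE` but is off by default: per-class counts arising
#' from simple random sampling drift around the global class ratio, which is
#' the behaviour the pipeline assumes.
#'
#' @param data A [labeled_dataset()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param stratify Logical; draw per-class instead of globally.
#' @return An object of class `split_result` with elements `train`, `test`,
#'   `fraction`, `seed`.
#' @export
random_split <- function(data, fraction, seed, stratify = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  check_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(data$features)
  n_train <- floor(fraction * n)
  if (n_train < 1L || n - n_train < 1L) {
    stop("degenerate split: need at least one training and one test row",
         call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    if (stratify) {
      idx <- integer(0)
      for (cl in c(0L, 1L)) {
        rows <- which(data$labels == cl)
        k <- round(fraction * length(rows))
        idx <- c(idx, sample(rows, k))
      }
      # adjust to hit floor(fraction * n) exactly
      pool <- setdiff(seq_len(n), idx)
      if (length(idx) > n_train) idx <- sample(idx, n_train)
      else if (length(idx) < n_train) {
        idx <- c(idx, sample(pool, n_train - length(idx)))
      }
      idx
    } else {
      sample(n, n_train)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(
    list(train = subset_rows(data, train_idx),
         test = subset_rows(data, test_idx),
         fraction = fraction, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> fraction=%.3g seed=%d: %d train / %d test\n",
              x$fraction, x$seed, nrow(x$train$features),
              nrow(x$test$features)))
  invisible(x)
}
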