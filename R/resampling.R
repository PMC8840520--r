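# SMOTE oversampling, random undersampling, and the class-inversion
# rebalancing that builds the minority-biased stage-2 training set.

#' SMOTE configuration
#'
#' @param K Positive integer: number of nearest minority neighbors each
#'   synthetic point interpolates toward (default 5).
#' @param seed Integer seed for neighbor choice and interpolation weights.
#' @param w Optional fixed interpolation weight in \[0, 1\] replacing the
#'   uniform draw; intended as a test hook (`w = 0` duplicates minority
#'   points exactly).
#' @return Object of class `smote_config`.
#' @export
smote_config <- function(K = 5L, seed = 0L, w = NULL) {
  check_scalar(K, "K", integer = TRUE)
  if (K < 1) stop("`K` must be a positive integer", call. = FALSE)
  if (!is.null(w)) {
    check_scalar(w, "w")
    if (w < 0 || w > 1) stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(K = as.integer(K), seed = as.integer(seed), w = w),
            class = "smote_config")
}

#' Generate synthetic minority samples with SMOTE
#'
#' Each synthetic point is `base + w * (neighbor - base)` where `base` is a
#' minority sample, `neighbor` is drawn uniformly from the base's `K`
#' nearest minority neighbors (Euclidean distance, minority points only),
#' and `w ~ Uniform[0, 1]`. Bases are cycled round-robin over the minority
#' rows; a non-multiple remainder is assigned to bases drawn at random
#' without replacement. Synthetic points therefore always lie on segments
#' between minority points, inside their axis-aligned bounding box.
#'
#' @param minority Numeric matrix of minority-class feature rows (>= 2 rows).
#' @param n_new Number of synthetic rows to generate (>= 0).
#' @param config A [smote_config()]. `K` is clamped to `nrow(minority) - 1`
#'   with a warning when too large.
#' @return Numeric matrix with `n_new` rows and `ncol(minority)` columns.
#' @export
smote_oversample <- function(minority, n_new, config = smote_config()) {
  stopifnot(inherits(config, "smote_config"))
  if (is.data.frame(minority)) minority <- as.matrix(minority)
  if (!is.matrix(minority)) minority <- matrix(minority, ncol = 1L)
  n_min <- nrow(minority)
  d <- ncol(minority)
  check_scalar(n_new, "n_new", integer = TRUE)
  if (n_new < 0) stop("`n_new` must be non-negative", call. = FALSE)
  if (n_new == 0L) {
    return(matrix(numeric(0), 0L, d, dimnames = list(NULL, colnames(minority))))
  }
  if (n_min < 2L) {
    stop("SMOTE requires at least 2 minority samples", call. = FALSE)
  }
  K <- config$K
  if (K >= n_min) {
    warning(sprintf("SMOTE K = %d >= minority size %d; clamping to %d",
                    K, n_min, n_min - 1L))
    K <- n_min - 1L
  }
  # K nearest minority neighbors of every minority point (self excluded)
  d2 <- outer(rowSums(minority^2), rowSums(minority^2), "+") -
    2 * tcrossprod(minority)
  diag(d2) <- Inf
  nn <- matrix(0L, n_min, K)
  for (i in seq_len(n_min)) {
    nn[i, ] <- order(d2[i, ], seq_len(n_min))[seq_len(K)]
  }
  with_seed(config$seed, {
    full <- n_new %/% n_min
    rem <- n_new %% n_min
    bases <- rep(seq_len(n_min), times = full)
    if (rem > 0L) bases <- c(bases, sample(n_min, rem))
    picks <- nn[cbind(bases, sample.int(K, n_new, replace = TRUE))]
    w <- if (is.null(config$w)) stats::runif(n_new) else rep(config$w, n_new)
    minority[bases, , drop = FALSE] +
      w * (minority[picks, , drop = FALSE] - minority[bases, , drop = FALSE])
  })
}

#' Randomly undersample rows of a matrix
#'
#' Draws `n_keep` rows uniformly without replacement, preserving the
#' original relative row order.
#'
#' @param samples Numeric matrix.
#' @param n_keep Number of rows to keep, `0 <= n_keep <= nrow(samples)`.
#' @param seed Integer seed.
#' @return Matrix of `n_keep` rows.
#' @export
random_undersample <- function(samples, n_keep, seed) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  n <- nrow(samples)
  check_scalar(n_keep, "n_keep", integer = TRUE)
  if (n_keep < 0 || n_keep > n) {
    stop(sprintf("`n_keep` must lie in [0, %d]", n), call. = FALSE)
  }
  keep <- with_seed(seed, sort(sample(n, n_keep)))
  samples[keep, , drop = FALSE]
}

#' Invert the class balance of a training set
#'
#' Builds the stage-2 training set: the majority class (0) is randomly
#' undersampled down to the original minority count, and the minority class
#' (1) is grown to the original majority count by keeping every original
#' minority row and appending SMOTE synthetics. Total size is preserved
#' exactly, so the new set carries the mirrored imbalance of the original.
#'
#' Class roles are taken from the labels (0 = majority, 1 = minority, as in
#' the conformational datasets this mirrors); if class 1 is not actually
#' the minority a warning is issued and the set is returned unchanged.
#'
#' @param train A [labeled_dataset()] containing both classes.
#' @param config A [smote_config()] used for the synthetic minority rows.
#' @param seed Integer seed governing the undersampling draw (SMOTE follows
#'   `config$seed`).
#' @return A [labeled_dataset()] of identical total size with swapped class
#'   counts; the attribute `"provenance"` flags each row `"original"` or
#'   `"smote"`.
#' @export
invert_class_balance <- function(train, config = smote_config(), seed = 0L) {
  stopifnot(inherits(train, "labeled_dataset"))
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop("single-class training set cannot be rebalanced", call. = FALSE)
  }
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  if (n1 > n0) {
    warning("class 1 is not the minority; returning the training set unchanged")
    out <- train
    attr(out, "provenance") <- rep("original", length(y))
    return(out)
  }
  maj <- train$features[y == 0L, , drop = FALSE]
  mino <- train$features[y == 1L, , drop = FALSE]
  maj_ids <- train$sample_ids[y == 0L]
  min_ids <- train$sample_ids[y == 1L]

  keep <- with_seed(seed, sort(sample(n0, n1)))
  maj_kept <- maj[keep, , drop = FALSE]
  synth <- smote_oversample(mino, n0 - n1, config)

  feats <- rbind(maj_kept, mino, synth)
  labels <- c(rep(0L, n1), rep(1L, n1), rep(1L, n0 - n1))
  ids <- c(as.character(maj_ids[keep]), as.character(min_ids),
           sprintf("smote_%d", seq_len(n0 - n1)))
  out <- labeled_dataset(feats, labels, feature_names = train$feature_names,
                         sample_ids = ids)
  attr(out, "provenance") <- c(rep("original", 2L * n1),
                               rep("smote", n0 - n1))
  out
}
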