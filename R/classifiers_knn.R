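# K-nearest neighbors with Euclidean distance and majority vote.

#' KNN configuration
#'
#' @param K Positive integer neighbor count (default 5).
#' @param standardize Z-score features on training statistics before
#'   computing distances (default TRUE; descriptor tables mix wildly
#'   different physical scales, which otherwise lets a single large-scale
#'   feature dominate the metric).
#' @return Object of class `knn_config`.
#' @export
knn_config <- function(K = 5L, standardize = TRUE) {
  check_scalar(K, "K", integer = TRUE)
  if (K < 1) stop("`K` must be a positive integer", call. = FALSE)
  structure(list(K = as.integer(K), standardize = isTRUE(standardize)),
            class = "knn_config")
}

#' Predict labels by K-nearest-neighbor majority vote
#'
#' For each query row, the `K` training points with smallest Euclidean
#' distance vote by majority. Distance ties are broken by lower training-row
#' index; vote ties (possible for even `K`) are broken by the label of the
#' single nearest neighbor. The returned `scores` are class-1 vote fractions,
#' usable as a ranking score for ROC analysis.
#'
#' @param train A [labeled_dataset()].
#' @param X Numeric matrix (or `labeled_dataset`) of query rows.
#' @param config A [knn_config()].
#' @return List with `labels` (integer 0/1) and `scores` (class-1 vote
#'   fraction in \[0, 1\]).
#' @export
predict_knn <- function(train, X, config = knn_config()) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(config, "knn_config"))
  if (inherits(X, "labeled_dataset")) X <- X$features
  Xt <- train$features
  if (!is.matrix(X)) X <- matrix(X, ncol = ncol(Xt))
  if (ncol(X) != ncol(Xt)) {
    stop(sprintf("dimension mismatch: train has %d features, X has %d columns",
                 ncol(Xt), ncol(X)), call. = FALSE)
  }
  n_train <- nrow(Xt)
  K <- config$K
  if (K > n_train) {
    stop(sprintf("K = %d exceeds the number of training samples (%d)",
                 K, n_train), call. = FALSE)
  }
  if (config$standardize) {
    ctr <- colMeans(Xt)
    scl <- apply(Xt, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xt <- sweep(sweep(Xt, 2L, ctr, "-"), 2L, scl, "/")
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  }
  y <- train$labels
  # squared Euclidean distances, train x query, via the expansion
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b ; monotone in true distance so ranking
  # and ties are identical.
  d2 <- outer(rowSums(Xt^2), rowSums(X^2), "+") - 2 * tcrossprod(Xt, X)
  n_query <- nrow(X)
  labels <- integer(n_query)
  scores <- numeric(n_query)
  for (j in seq_len(n_query)) {
    ord <- order(d2[, j], seq_len(n_train))[seq_len(K)]
    votes1 <- sum(y[ord])
    scores[j] <- votes1 / K
    labels[j] <- if (2L * votes1 > K) 1L
                 else if (2L * votes1 < K) 0L
                 else y[ord[1L]]
  }
  list(labels = labels, scores = scores)
}
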