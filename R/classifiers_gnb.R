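# Gaussian naive Bayes, fitted from scratch via per-class sample moments.
# Note: the abbreviation "GB" in the conformational-selection literature this
# package serves denotes Gaussian (naive) Bayes, not gradient boosting.

#' Fit a Gaussian naive Bayes classifier
#'
#' Class priors are the training class frequencies; per-class per-feature
#' means and variances are the sample moments with population divisor
#' `n_class`. Variances are clamped from below by `var_floor` so constant
#' features cannot produce degenerate densities. No feature standardization
#' is applied: the Gaussian likelihood is scale-equivariant.
#'
#' @param train A [labeled_dataset()] containing both classes.
#' @param var_floor Positive variance floor. The default `NULL` uses
#'   `1e-9 * max(per-feature variance across classes)`, falling back to
#'   `1e-12` when all variances are zero.
#' @return Object of class `gnb_model` with `priors` (length-2, classes 0/1),
#'   `means` and `variances` (2 x d matrices, rows = classes 0/1), and
#'   `var_floor`.
#' @export
fit_gaussian_nb <- function(train, var_floor = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop("single-class training set: both classes required to fit", call. = FALSE)
  }
  X <- train$features
  d <- ncol(X)
  mu <- matrix(0, 2L, d, dimnames = list(c("0", "1"), colnames(X)))
  va <- mu
  for (cl in c(0L, 1L)) {
    Xc <- X[y == cl, , drop = FALSE]
    m <- colMeans(Xc)
    mu[cl + 1L, ] <- m
    va[cl + 1L, ] <- colMeans(sweep(Xc, 2L, m, "-")^2)  # population variance
  }
  if (is.null(var_floor)) {
    vmax <- max(va)
    var_floor <- if (vmax > 0) 1e-9 * vmax else 1e-12
  }
  check_scalar(var_floor, "var_floor")
  if (var_floor <= 0) stop("`var_floor` must be positive", call. = FALSE)
  va <- pmax(va, var_floor)
  priors <- c(mean(y == 0L), mean(y == 1L))
  names(priors) <- c("0", "1")
  structure(
    list(priors = priors, means = mu, variances = va, var_floor = var_floor,
         feature_names = train$feature_names),
    class = "gnb_model"
  )
}

#' @export
print.gnb_model <- function(x, ...) {
  cat(sprintf("<gnb_model> %d features, priors = (%.3f, %.3f)\n",
              ncol(x$means), x$priors[1L], x$priors[2L]))
  invisible(x)
}

#' Predict with a fitted Gaussian naive Bayes model
#'
#' Sums per-feature Gaussian log-likelihoods (naive conditional
#' independence), adds the log prior, and normalizes across the two classes
#' with a log-sum-exp to obtain posteriors. The MAP label is the posterior
#' argmax; exact ties go to class 0.
#'
#' @param model A `gnb_model` from [fit_gaussian_nb()].
#' @param X Numeric matrix (or `labeled_dataset`) with matching columns.
#' @return List with `posteriors` (n x 2 matrix, columns classes 0/1) and
#'   `labels` (integer 0/1).
#' @export
predict_gaussian_nb <- function(model, X) {
  stopifnot(inherits(model, "gnb_model"))
  if (inherits(X, "labeled_dataset")) X <- X$features
  if (!is.matrix(X)) X <- matrix(X, ncol = ncol(model$means))
  d <- ncol(model$means)
  if (ncol(X) != d) {
    stop(sprintf("dimension mismatch: model has %d features, X has %d columns",
                 d, ncol(X)), call. = FALSE)
  }
  logpost <- matrix(0, nrow(X), 2L)
  for (cl in 1:2) {
    mu <- model$means[cl, ]
    va <- model$variances[cl, ]
    ll <- -0.5 * (sweep(X, 2L, mu, "-")^2) / matrix(va, nrow(X), d, byrow = TRUE)
    ll <- ll - 0.5 * matrix(log(2 * pi * va), nrow(X), d, byrow = TRUE)
    logpost[, cl] <- rowSums(ll) + log(model$priors[cl])
  }
  m <- pmax(logpost[, 1L], logpost[, 2L])
  lse <- m + log(exp(logpost[, 1L] - m) + exp(logpost[, 2L] - m))
  post <- exp(logpost - lse)
  colnames(post) <- c("0", "1")
  list(posteriors = post,
       labels = as.integer(post[, 2L] > post[, 1L]))  # ties -> class 0
}
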