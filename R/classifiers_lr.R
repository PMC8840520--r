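# Logistic regression with cross-entropy cost, fitted from scratch by
# deterministic batch gradient descent with backtracking line search.

# Penalized mean cross-entropy and its gradient. beta = c(b0, b1..bd) on
# the (optionally standardized) feature scale; the intercept is unpenalized.
lr_cost <- function(beta, X, y, C) {
  z <- drop(beta[1L] + X %*% beta[-1L])
  ce <- mean(log1pexp(z) - y * z)
  ce + sum(beta[-1L]^2) / (2 * C)
}

lr_grad <- function(beta, X, y, C) {
  z <- drop(beta[1L] + X %*% beta[-1L])
  p <- stats::plogis(z)
  r <- p - y
  n <- length(y)
  c(mean(r), drop(crossprod(X, r)) / n + beta[-1L] / C)
}

#' Fit a binary logistic regression classifier
#'
#' Minimizes the mean cross-entropy between labels and predicted
#' probabilities plus an L2 penalty `1/(2C) * sum(beta_j^2)` on the
#' non-intercept weights. `C` is the usual inverse regularization strength
#' (larger C, weaker penalty). Optimization is deterministic batch gradient
#' descent from the zero vector with Armijo backtracking, so results do not
#' depend on any random seed.
#'
#' Features are z-scored on the training set by default (`standardize`);
#' the scaling constants are stored in the model and re-applied at
#' prediction time. Reported coefficients are on the standardized scale.
#'
#' @param train A [labeled_dataset()] containing both classes.
#' @param C Positive inverse regularization strength (default 5).
#' @param max_iter Maximum gradient-descent iterations.
#' @param tol Convergence tolerance on the cost decrease.
#' @param threshold Decision threshold on the predicted probability; class 1
#'   is assigned when probability >= threshold.
#' @param standardize Z-score features on training statistics (default TRUE).
#' @return An object of class `lr_model` with elements `intercept`,
#'   `weights`, `C`, `threshold`, `center`, `scale`, `cost`, `iterations`,
#'   `converged`.
#' @export
fit_logistic <- function(train, C = 5, max_iter = 500L, tol = 1e-8,
                         threshold = 0.5, standardize = TRUE) {
  stopifnot(inherits(train, "labeled_dataset"))
  check_scalar(C, "C")
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  y <- train$labels
  if (length(unique(y)) < 2L) {
    stop("single-class training set: both classes required to fit", call. = FALSE)
  }
  X <- train$features
  d <- ncol(X)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  } else {
    ctr <- rep(0, d)
    scl <- rep(1, d)
  }

  beta <- rep(0, d + 1L)
  cost <- lr_cost(beta, X, y, C)
  if (!is.finite(cost)) stop("non-finite cost at initialization", call. = FALSE)
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- lr_grad(beta, X, y, C)
    gg <- sum(g^2)
    # Armijo backtracking on the full-batch objective
    repeat {
      cand <- beta - step * g
      cand_cost <- lr_cost(cand, X, y, C)
      if (is.finite(cand_cost) && cand_cost <= cost - 0.5 * step * gg) break
      step <- step / 2
      if (step < 1e-14) break
    }
    if (step < 1e-14) break
    beta <- cand
    if (cost - cand_cost < tol) {
      cost <- cand_cost
      converged <- TRUE
      break
    }
    cost <- cand_cost
    step <- min(step * 2, 1e4)
  }
  if (!is.finite(cost)) {
    stop("non-finite cost during optimization", call. = FALSE)
  }
  structure(
    list(intercept = beta[1L], weights = beta[-1L], C = C,
         threshold = threshold, center = ctr, scale = scl,
         feature_names = train$feature_names,
         cost = cost, iterations = iter, converged = converged),
    class = "lr_model"
  )
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf(
    "<lr_model> %d features, C=%g, cost=%.6g, %d iterations (%s)\n",
    length(x$weights), x$C, x$cost, x$iterations,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Predict with a fitted logistic regression model
#'
#' Computes `p = plogis(b0 + x' beta)` on the model's standardized feature
#' scale and assigns class 1 when `p >= threshold`.
#'
#' @param model An `lr_model` from [fit_logistic()].
#' @param X Numeric matrix (or `labeled_dataset`) with the model's number of
#'   columns.
#' @return List with `probabilities` (numeric in \[0, 1\]) and `labels`
#'   (integer 0/1).
#' @export
predict_logistic <- function(model, X) {
  stopifnot(inherits(model, "lr_model"))
  if (inherits(X, "labeled_dataset")) X <- X$features
  if (!is.matrix(X)) X <- matrix(X, ncol = length(model$weights))
  if (ncol(X) != length(model$weights)) {
    stop(sprintf("dimension mismatch: model has %d features, X has %d columns",
                 length(model$weights), ncol(X)), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  z <- drop(model$intercept + Xs %*% model$weights)
  p <- stats::plogis(z)
  list(probabilities = p,
       labels = as.integer(p >= model$threshold))
}
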