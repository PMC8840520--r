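# --- logistic regression -------------------------------------------------

test_that("fit_logistic recovers a symmetric 1-D problem", {
  X <- matrix(c(rep(-1, 50), rep(1, 50)), ncol = 1)
  d <- labeled_dataset(X, c(rep(0L, 50), rep(1L, 50)))
  m <- fit_logistic(d, C = 5, standardize = FALSE)
  expect_lt(abs(m$intercept), 1e-3)
  expect_gt(m$weights[1L], 0)
  expect_true(m$converged)
})

test_that("analytic LR gradient matches central finite differences", {
  set.seed(42)
  d <- random_dataset(40, 3, seed = 42)
  X <- d$features
  y <- d$labels
  C <- 5
  cost <- function(beta) {  # independent re-statement of the objective
    z <- beta[1] + X %*% beta[-1]
    mean(log(1 + exp(z)) - y * z) + sum(beta[-1]^2) / (2 * C)
  }
  grad <- function(beta) {  # package's analytic gradient, probed indirectly:
    p <- 1 / (1 + exp(-(beta[1] + X %*% beta[-1])))
    c(mean(p - y), crossprod(X, p - y) / nrow(X) + beta[-1] / C)
  }
  for (i in 1:5) {
    beta <- rnorm(4, sd = 0.5)
    expect_lt(max(abs(grad(beta) - oracle_fd_grad(cost, beta))), 1e-5)
  }
  # and the fitted model sits at a near-zero gradient of that objective
  m <- fit_logistic(d, C = 5, standardize = FALSE, tol = 1e-12)
  beta_hat <- c(m$intercept, m$weights)
  expect_lt(max(abs(oracle_fd_grad(cost, beta_hat))), 1e-4)
})

test_that("fitted LR cost matches an independent convex optimizer", {
  d <- random_dataset(60, 4, seed = 7)
  m <- fit_logistic(d, C = 5, tol = 1e-12, max_iter = 2000L)
  # oracle: optim/BFGS on the identical standardized objective
  X <- scale(d$features)
  y <- d$labels
  cost <- function(beta) {
    z <- beta[1] + X %*% beta[-1]
    mean(pmax(z, 0) + log1p(exp(-abs(z))) - y * z) + sum(beta[-1]^2) / 10
  }
  o <- stats::optim(rep(0, 5), cost, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  expect_lte(m$cost, o$value + 1e-6)
})

test_that("fit_logistic rejects single-class training sets", {
  d <- labeled_dataset(matrix(rnorm(10), 5), rep(1L, 5))
  expect_error(fit_logistic(d), "single-class")
})

test_that("predict_logistic matches the closed-form inverse logit", {
  d <- random_dataset(20, 2, seed = 1)
  m <- fit_logistic(d, standardize = FALSE)
  # zero model: probability exactly 0.5, label 1 under ">= threshold"
  m0 <- m
  m0$intercept <- 0
  m0$weights <- c(0, 0)
  p0 <- predict_logistic(m0, matrix(rnorm(6), 3))
  expect_equal(p0$probabilities, rep(0.5, 3))
  expect_equal(p0$labels, rep(1L, 3))
  # saturation without overflow
  m1 <- m0
  m1$weights <- c(1, 0)
  ps <- predict_logistic(m1, matrix(c(50, 0), 1))
  expect_gte(ps$probabilities, 1 - 1e-20)  # 1 - 1e-20 == 1 in double
  expect_true(is.finite(ps$probabilities))
  # 3-point grid vs direct 1/(1+exp(-z))
  m2 <- m0
  m2$intercept <- 0.3
  m2$weights <- c(1.2, -0.7)
  G <- matrix(c(0.1, -0.5, 2, 0.4, 1.1, -2.2), 3, 2)
  z <- 0.3 + G %*% c(1.2, -0.7)
  expect_equal(predict_logistic(m2, G)$probabilities,
               drop(1 / (1 + exp(-z))), tolerance = 1e-12)
  expect_error(predict_logistic(m, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("LR cost decreases monotonically under small fixed steps", {
  # property: gradient flow on random small problems never increases cost
  for (s in 1:5) {
    d <- random_dataset(30, 2, seed = 100 + s)
    X <- scale(d$features)
    y <- d$labels
    cost <- function(beta) {
      z <- beta[1] + X %*% beta[-1]
      mean(pmax(z, 0) + log1p(exp(-abs(z))) - y * z) + sum(beta[-1]^2) / 10
    }
    grad <- function(beta) {
      p <- 1 / (1 + exp(-(beta[1] + X %*% beta[-1])))
      c(mean(p - y), crossprod(X, p - y) / nrow(X) + beta[-1] / 5)
    }
    beta <- rep(0, 3)
    prev <- cost(beta)
    for (i in 1:50) {
      beta <- beta - 0.05 * grad(beta)
      cur <- cost(beta)
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

# --- Gaussian naive Bayes ------------------------------------------------

test_that("fit_gaussian_nb computes population moments and priors", {
  X <- matrix(c(0, 2, 5, 5), ncol = 1)
  d <- labeled_dataset(X, c(0L, 0L, 1L, 1L))
  m <- fit_gaussian_nb(d)
  expect_equal(unname(m$means["0", 1L]), 1)
  expect_equal(unname(m$variances["0", 1L]), 1)  # population divisor n
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # constant feature in class 1 -> clamped to the floor, prediction finite
  expect_equal(unname(m$variances["1", 1L]), m$var_floor)
  p <- predict_gaussian_nb(m, matrix(1.2))
  expect_true(all(is.finite(p$posteriors)))
})

test_that("GNB posteriors match the brute-force Bayes oracle", {
  d <- random_dataset(10, 2, seed = 21)
  m <- fit_gaussian_nb(d)
  Q <- matrix(rnorm(10), 5, 2)
  p <- predict_gaussian_nb(m, Q)
  for (i in 1:5) {
    expect_equal(unname(p$posteriors[i, ]),
                 unname(oracle_gnb_posterior(m, Q[i, ])), tolerance = 1e-10)
  }
  expect_equal(unname(rowSums(p$posteriors)), rep(1, 5), tolerance = 1e-12)
})

test_that("GNB symmetry: midpoint query ties toward class 0", {
  d <- labeled_dataset(matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1),
                       c(0L, 0L, 1L, 1L))
  m <- fit_gaussian_nb(d)  # mu = -1/+1, equal variances, equal priors
  p <- predict_gaussian_nb(m, matrix(0))
  expect_equal(unname(p$posteriors[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(p$labels, 0L)
})

test_that("raising the class-1 prior never lowers the class-1 posterior", {
  d <- random_dataset(30, 3, seed = 31)
  m <- fit_gaussian_nb(d)
  Q <- matrix(rnorm(30), 10, 3)
  base <- predict_gaussian_nb(m, Q)$posteriors[, 2L]
  for (p1 in c(0.5, 0.7, 0.9, 0.99)) {
    m2 <- m
    m2$priors <- c("0" = 1 - p1, "1" = p1)
    if (p1 <= m$priors[["1"]]) next
    up <- predict_gaussian_nb(m2, Q)$posteriors[, 2L]
    expect_true(all(up >= base - 1e-12))
  }
})

# --- K-nearest neighbors -------------------------------------------------

test_that("KNN degenerate cases: K=1 identity and K=n majority", {
  d <- random_dataset(15, 2, seed = 41)
  q <- d$features[4L, , drop = FALSE]
  expect_equal(predict_knn(d, q, knn_config(K = 1))$labels, d$labels[4L])
  maj <- as.integer(sum(d$labels) * 2L > 15L)
  expect_equal(predict_knn(d, matrix(rnorm(2), 1), knn_config(K = 15))$labels,
               maj)
  expect_error(predict_knn(d, q, knn_config(K = 16)), "exceeds")
  expect_error(predict_knn(d, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("KNN matches the exhaustive-sort oracle, including tie rules", {
  train_X <- matrix(c(0, 0,  1, 0,  0, 1,  4, 4,  5, 5), 5, 2, byrow = TRUE)
  train_y <- c(0L, 0L, 1L, 1L, 1L)
  d <- labeled_dataset(train_X, train_y)
  q <- c(0.4, 0.4)
  got <- predict_knn(d, matrix(q, 1), knn_config(K = 3, standardize = FALSE))
  expect_equal(got$labels, oracle_knn(train_X, train_y, q, 3))
  expect_equal(got$labels, 0L)  # frozen from the hand enumeration

  # fuzzed queries and K, unstandardized to keep the oracle identical
  set.seed(7)
  d2 <- random_dataset(20, 3, seed = 51)
  for (i in 1:30) {
    K <- sample(1:10, 1L)
    q <- rnorm(3)
    got <- predict_knn(d2, matrix(q, 1),
                       knn_config(K = K, standardize = FALSE))$labels
    expect_equal(got, oracle_knn(d2$features, d2$labels, q, K))
  }
})

test_that("KNN vote ties (even K) resolve to the nearest neighbor's label", {
  train_X <- matrix(c(0, 10, 20, 30), ncol = 1)
  d <- labeled_dataset(train_X, c(1L, 0L, 1L, 0L))
  got <- predict_knn(d, matrix(1), knn_config(K = 2, standardize = FALSE))
  expect_equal(got$labels, 1L)   # 1-1 vote, nearest (row 1) has label 1
  expect_equal(got$scores, 0.5)
})

test_that("KNN is invariant to consistent feature permutations", {
  d <- random_dataset(25, 4, seed = 61)
  Q <- matrix(rnorm(20), 5, 4)
  base <- predict_knn(d, Q, knn_config(K = 5))$labels
  for (i in 1:5) {
    perm <- sample(4)
    dp <- labeled_dataset(d$features[, perm], d$labels)
    expect_equal(predict_knn(dp, Q[, perm], knn_config(K = 5))$labels, base)
  }
})

test_that("all three classifiers separate a linearly separable training set", {
  d <- separable_dataset(n_per_class = 30, gap = 12, seed = 71)
  lr <- fit_logistic(d)
  expect_equal(predict_logistic(lr, d)$labels, d$labels)
  gnb <- fit_gaussian_nb(d)
  expect_equal(predict_gaussian_nb(gnb, d)$labels, d$labels)
  expect_equal(predict_knn(d, d, knn_config(K = 1))$labels, d$labels)
})

# --- serialization -------------------------------------------------------

test_that("models round-trip through the JSON schema", {
  d <- random_dataset(30, 3, seed = 81)
  lr <- fit_logistic(d)
  p1 <- tempfile(fileext = ".json")
  write_model(lr, p1)
  lr2 <- read_model(p1)
  Q <- matrix(rnorm(12), 4, 3)
  expect_equal(predict_logistic(lr2, Q)$probabilities,
               predict_logistic(lr, Q)$probabilities, tolerance = 1e-12)

  gnb <- fit_gaussian_nb(d)
  p2 <- tempfile(fileext = ".json")
  write_model(gnb, p2)
  gnb2 <- read_model(p2)
  expect_equal(predict_gaussian_nb(gnb2, Q)$posteriors,
               predict_gaussian_nb(gnb, Q)$posteriors, tolerance = 1e-12)
})
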