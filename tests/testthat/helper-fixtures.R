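# Shared fixtures: tiny datasets built in code, plus independent brute-force
# oracles kept deliberately separate from the package implementation.

# Random small labeled dataset with both classes guaranteed present.
random_dataset <- function(n, d, p1 = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    labels <- rbinom(n, 1L, p1)
    if (length(unique(labels)) == 2L) break
  }
  labeled_dataset(matrix(rnorm(n * d), n, d), labels)
}

# Two well-separated Gaussian blobs (linearly separable for large gap).
separable_dataset <- function(n_per_class = 30, d = 3, gap = 12, seed = 1) {
  set.seed(seed)
  X0 <- matrix(rnorm(n_per_class * d), n_per_class, d)
  X1 <- matrix(rnorm(n_per_class * d) + gap, n_per_class, d)
  labeled_dataset(rbind(X0, X1), c(rep(0L, n_per_class), rep(1L, n_per_class)))
}

write_csv_fixture <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}

# --- independent oracles -------------------------------------------------

# Brute-force Bayes posterior: explicit Gaussian density products and the
# explicit normalizer P(x), no logs.
oracle_gnb_posterior <- function(model, x) {
  dens <- function(cl) {
    prod(stats::dnorm(x, model$means[cl, ], sqrt(model$variances[cl, ]))) *
      model$priors[cl]
  }
  joint <- c(dens(1L), dens(2L))
  joint / sum(joint)
}

# Exhaustive KNN: full distance sort with the package's documented tie rules.
oracle_knn <- function(train_X, train_y, x, K) {
  d <- sqrt(colSums((t(train_X) - x)^2))
  ord <- order(d, seq_along(d))[seq_len(K)]
  v1 <- sum(train_y[ord])
  if (2 * v1 > K) 1L else if (2 * v1 < K) 0L else train_y[ord[1L]]
}

# Mann-Whitney AUC: exhaustive pair counting, ties counted half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1L]
  neg <- s[y == 0L]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Central finite-difference gradient of f at x.
oracle_fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
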