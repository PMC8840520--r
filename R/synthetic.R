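# Seeded generator of imbalanced two-class Gaussian descriptor tables.
#
# Emulates the statistical shape of real conformational descriptor tables:
# ~3000 rows, ~50 continuous features on heterogeneous physical scales,
# severe class imbalance (3:1 or 20:1), and a tunable degree of class
# separation. Descriptor VALUES are synthetic; nothing here is a physically
# meaningful molecular property.

#' Specification for a synthetic imbalanced descriptor table
#'
#' The two classes share an equicorrelated covariance whose per-feature
#' standard deviations are log-spaced over `feature_scale_spread`; the
#' class-mean difference is scaled so its Mahalanobis norm equals
#' `separation`. Class 1 is the minority.
#'
#' @param n_samples Total number of rows.
#' @param n_features Number of descriptor columns (default 50).
#' @param imbalance_ratio Majority:minority ratio `r >= 1`; the minority
#'   count is `round(n_samples / (r + 1))` unless overridden.
#' @param separation Mahalanobis distance between class means (>= 0).
#' @param feature_scale_spread Ratio of largest to smallest feature standard
#'   deviation (>= 1), emulating mixed physical scales.
#' @param correlation Common pairwise feature correlation in \[0, 1).
#' @param n_minority Optional explicit minority count overriding the ratio
#'   (used to reproduce exact published class counts such as 850/2147).
#' @param marginal `"gaussian"` or `"lognormal"`; the latter exponentiates
#'   the latent Gaussian features (model mismatch for a Gaussian NB learner),
#'   letting tests separate algorithm bugs from model misfit.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_samples, n_features = 50L, imbalance_ratio = 3,
                           separation = 1.5, feature_scale_spread = 1,
                           correlation = 0, n_minority = NULL,
                           marginal = c("gaussian", "lognormal"), seed = 0L) {
  check_scalar(n_samples, "n_samples", integer = TRUE)
  check_scalar(n_features, "n_features", integer = TRUE)
  check_scalar(imbalance_ratio, "imbalance_ratio")
  check_scalar(separation, "separation")
  check_scalar(feature_scale_spread, "feature_scale_spread")
  check_scalar(correlation, "correlation")
  marginal <- match.arg(marginal)
  if (imbalance_ratio < 1) stop("`imbalance_ratio` must be >= 1", call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  if (feature_scale_spread < 1) {
    stop("`feature_scale_spread` must be >= 1", call. = FALSE)
  }
  if (correlation < 0 || correlation >= 1) {
    stop("`correlation` must lie in [0, 1)", call. = FALSE)
  }
  n_min <- if (is.null(n_minority)) {
    as.integer(round(n_samples / (imbalance_ratio + 1)))
  } else {
    check_scalar(n_minority, "n_minority", integer = TRUE)
    as.integer(n_minority)
  }
  if (n_min < 2L || n_samples - n_min < 2L) {
    stop("infeasible spec: each class needs at least 2 samples", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
         imbalance_ratio = imbalance_ratio, separation = separation,
         feature_scale_spread = feature_scale_spread,
         correlation = correlation, n_minority = n_min,
         marginal = marginal, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Generate a synthetic imbalanced descriptor table
#'
#' Draws `n_samples - n_minority` majority (class 0) and `n_minority`
#' minority (class 1) rows from two multivariate Gaussians sharing the
#' covariance `Sigma = D R D` (`R` equicorrelated with the spec's
#' `correlation`, `D` log-spaced scales), with the mean difference drawn
#' once per seed and rescaled so that its Mahalanobis norm equals the
#' spec's `separation`. Class counts are exact, never binomially sampled.
#' Rows are shuffled so classes are interleaved; feature names are
#' `pro_f01`, `pro_f02`, ...
#'
#' @param spec A [generator_spec()].
#' @return A [labeled_dataset()] with attribute `"manifest"` recording the
#'   spec (suitable for JSON provenance).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$n_features
  n1 <- spec$n_minority
  n0 <- spec$n_samples - n1
  scales <- if (spec$feature_scale_spread > 1) {
    exp(seq(0, log(spec$feature_scale_spread), length.out = d))
  } else {
    rep(1, d)
  }
  rho <- spec$correlation

  with_seed(spec$seed, {
    # latent correlated standard normals: equicorrelated R has the
    # one-factor representation  z = sqrt(rho) g + sqrt(1-rho) e
    n <- spec$n_samples
    e <- matrix(stats::rnorm(n * d), n, d)
    z <- if (rho > 0) {
      sqrt(rho) * matrix(stats::rnorm(n), n, d) + sqrt(1 - rho) * e
    } else {
      e
    }
    # mean shift with Mahalanobis norm = separation: pick a latent-space
    # direction u, then delta = sep * u / ||u|| on the latent scale, which
    # maps through D to the feature scale with the same Mahalanobis norm.
    u <- stats::rnorm(d)
    u <- u / sqrt(sum(u^2))
    # whitened-space direction -> latent correlated space via R^(1/2)
    if (rho > 0) {
      ones <- rep(1 / sqrt(d), d)
      a <- sqrt(1 - rho + d * rho)
      b <- sqrt(1 - rho)
      proj <- sum(u * ones)
      u <- a * proj * ones + b * (u - proj * ones)
    }
    delta <- spec$separation * u
    labels <- c(rep(0L, n0), rep(1L, n1))
    z[labels == 1L, ] <- sweep(z[labels == 1L, , drop = FALSE], 2L, delta, "+")
    X <- if (spec$marginal == "lognormal") {
      sweep(exp(z), 2L, scales, "*")  # lognormal marginals, same scale spread
    } else {
      sweep(z, 2L, scales, "*")
    }
    perm <- sample(n)
    X <- X[perm, , drop = FALSE]
    labels <- labels[perm]
    colnames(X) <- sprintf("pro_f%02d", seq_len(d))
    out <- labeled_dataset(X, labels)
    attr(out, "manifest") <- unclass(spec)
    out
  })
}

#' Write a generated dataset plus its provenance manifest
#'
#' @param data A dataset from [generate_dataset()].
#' @param path CSV output path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @param label_column Label column name.
#' @return `path`, invisibly.
#' @export
write_generated <- function(data, path, label_column = "active_binding") {
  write_dataset(data, path, label_column = label_column)
  manifest <- attr(data, "manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
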