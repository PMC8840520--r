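# SMOTE, random undersampling, class-inversion rebalancing.

test_that("smote_oversample interpolates between minority neighbors", {
  # two identical points: every synthetic equals that point
  mino <- matrix(rep(c(2, 3), each = 2), 2, 2)
  syn <- smote_oversample(mino, 10L, smote_config(K = 1, seed = 1))
  expect_equal(dim(syn), c(10L, 2L))
  expect_true(all(syn[, 1] == 2) && all(syn[, 2] == 3))

  # {0, 10} in 1-D: synthetics in [0, 10], mean near 5 by uniform weights
  mino <- matrix(c(0, 10), ncol = 1)
  syn <- smote_oversample(mino, 100L, smote_config(K = 1, seed = 2))
  expect_true(all(syn >= 0 & syn <= 10))
  expect_gt(mean(syn), 3)
  expect_lt(mean(syn), 7)

  # n_new = 0: empty matrix with d columns
  z <- smote_oversample(matrix(rnorm(8), 4, 2), 0L, smote_config())
  expect_equal(dim(z), c(0L, 2L))
})

test_that("smote contracts: errors, K clamp, determinism, w hook", {
  expect_error(smote_oversample(matrix(1, 1, 2), 5L, smote_config()),
               "at least 2 minority samples")
  mino <- matrix(rnorm(6), 3, 2)
  expect_warning(syn <- smote_oversample(mino, 4L, smote_config(K = 5, seed = 3)),
                 "clamping")
  expect_equal(nrow(syn), 4L)

  a <- smote_oversample(mino, 7L, smote_config(K = 2, seed = 9))
  b <- smote_oversample(mino, 7L, smote_config(K = 2, seed = 9))
  expect_identical(a, b)

  # w = 0 test hook: every synthetic duplicates an original minority row
  syn0 <- smote_oversample(mino, 9L, smote_config(K = 2, seed = 4, w = 0))
  match_row <- apply(syn0, 1L, function(r) {
    any(apply(mino, 1L, function(m) all(m == r)))
  })
  expect_true(all(match_row))
})

test_that("SMOTE synthetics lie in the minority bounding box (property)", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:20, 1L)
    dcol <- sample(1:6, 1L)
    mino <- matrix(rnorm(n * dcol, sd = 5), n, dcol)
    syn <- suppressWarnings(
      smote_oversample(mino, sample(0:40, 1L),
                       smote_config(K = sample(1:6, 1L), seed = i)))
    if (nrow(syn) == 0L) next
    lo <- apply(mino, 2L, min)
    hi <- apply(mino, 2L, max)
    expect_true(all(t(syn) >= lo - 1e-12) && all(t(syn) <= hi + 1e-12))
  }
})

test_that("random_undersample keeps order, reproduces per seed", {
  X <- matrix(seq_len(40), 20, 2)
  expect_identical(random_undersample(X, 20L, seed = 1), X)
  kept <- random_undersample(X, 8L, seed = 1)
  expect_equal(nrow(kept), 8L)
  expect_true(all(kept[, 1L] %in% X[, 1L]))
  expect_true(!is.unsorted(kept[, 1L]))  # original relative order
  expect_identical(kept, random_undersample(X, 8L, seed = 1))
  expect_error(random_undersample(X, 21L, seed = 1), "n_keep")

  # different seeds give different subsets with overwhelming probability
  X2 <- matrix(rnorm(100), 100, 1)
  diffs <- vapply(1:5, function(s) {
    !identical(random_undersample(X2, 50L, seed = s),
               random_undersample(X2, 50L, seed = s + 1000L))
  }, logical(1))
  expect_true(all(diffs))
})

test_that("invert_class_balance swaps class counts and preserves size", {
  # the published 30% case: (628, 271) -> (271, 628), total 899
  d <- random_dataset(899, 3, seed = 1)
  d$labels <- c(rep(0L, 628), rep(1L, 271))[order(rnorm(899))]
  inv <- invert_class_balance(d, smote_config(K = 5, seed = 2), seed = 3)
  expect_equal(unname(class_counts(inv)), c(271L, 628L))
  expect_equal(nrow(inv$features), 899L)

  # a 20:1-style case: (574, 25) -> (25, 574)
  d2 <- random_dataset(599, 2, seed = 2)
  d2$labels <- c(rep(0L, 574), rep(1L, 25))
  inv2 <- invert_class_balance(d2, smote_config(K = 5, seed = 2), seed = 3)
  expect_equal(unname(class_counts(inv2)), c(25L, 574L))

  # balanced input is a fixed point
  d3 <- random_dataset(40, 2, seed = 3)
  d3$labels <- rep(c(0L, 1L), 20)
  inv3 <- invert_class_balance(d3, smote_config(seed = 1), seed = 1)
  expect_equal(unname(class_counts(inv3)), c(20L, 20L))
})

test_that("inversion retains all original minority rows unchanged", {
  set.seed(6)
  for (i in 1:30) {
    n0 <- sample(6:60, 1L)
    n1 <- sample(2:n0, 1L)
    feats <- matrix(rnorm((n0 + n1) * 3), n0 + n1, 3)
    d <- labeled_dataset(feats, c(rep(0L, n0), rep(1L, n1)))
    inv <- suppressWarnings(
      invert_class_balance(d, smote_config(K = 3, seed = i), seed = i))
    expect_equal(nrow(inv$features), n0 + n1)          # size preserved
    expect_equal(sum(inv$labels == 0L), n1)            # counts swapped
    expect_equal(sum(inv$labels == 1L), n0)
    prov <- attr(inv, "provenance")
    orig1 <- inv$features[inv$labels == 1L & prov == "original", , drop = FALSE]
    expect_equal(nrow(orig1), n1)
    expect_equal(orig1, d$features[d$labels == 1L, , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("inversion warns and no-swaps when class 1 is not the minority", {
  d <- labeled_dataset(matrix(rnorm(20), 10), c(rep(0L, 3), rep(1L, 7)))
  expect_warning(inv <- invert_class_balance(d, smote_config(seed = 1), 1),
                 "not the minority")
  expect_equal(unname(class_counts(inv)), c(3L, 7L))
  expect_error(invert_class_balance(
    labeled_dataset(matrix(rnorm(10), 5), rep(0L, 5))), "single-class")
})
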