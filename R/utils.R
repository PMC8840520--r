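# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG to a reproducible state derived from `seed`, evaluates
#' `expr`, and restores the caller's RNG state on exit, so that seeded
#' package functions never perturb the user's random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed and a stage tag, keeping the result
# inside the positive 32-bit integer range. All pipeline randomness flows
# from one root seed through this derivation.
derive_seed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

# Assert that x is a single finite number; name used in the error message.
check_scalar <- function(x, name, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != trunc(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# log(1 + exp(z)) without overflow for large |z|.
log1pexp <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}
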