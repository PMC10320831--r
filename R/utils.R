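# Shared numerical helpers. All randomness in the package flows through
# explicit integer seeds; derive_seed() splits a master seed into
# per-component streams so stages can be re-run independently.

#' Derive a component seed from a master seed
#'
#' Deterministically maps a master seed plus a character label to a new
#' 31-bit seed, so that independent pipeline stages consume independent
#' random streams without hidden global state.
#'
#' @param seed Integer master seed.
#' @param label Character stream label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer(((abs(seed) %% 1000003) * 2038074743 + h * 97) %% 2147483647)
}

#' Numerically stable two-option softmax
#'
#' @param dv Numeric matrix (n trials x 2 options) of decision values, or a
#'   length-2 vector.
#' @return Matrix of choice probabilities with rows summing to 1.
#' @export
softmax2 <- function(dv) {
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1L)
  stopifnot(ncol(dv) == 2L)
  m <- pmax(dv[, 1L], dv[, 2L])
  e <- exp(dv - m)
  e / rowSums(e)
}

#' Population moments of a probability vector
#'
#' Mean, population variance (divide by n), and standardized skewness of a
#' set of item reward probabilities. Skewness of a zero-variance vector is
#' defined as 0.
#'
#' @param x Numeric vector of probabilities (or any values).
#' @return Named list with `mean`, `variance`, `skewness`.
#' @export
moments <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- if (v < 1e-12) 0 else mean((x - m)^3) / v^1.5
  list(mean = m, variance = v, skewness = s)
}

# z-score that maps a constant column to all zeros instead of NaN
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# run fn under a local RNG state so package functions never disturb the
# caller's .Random.seed
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# deterministic integer allocation of n into length(p) cells proportional to
# p: floor counts, then remainders assigned by largest fractional part
# (ties broken by cell order). Guarantees sum == n and exact realized
# proportions whenever n * p is integral.
allocate_counts <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9, n >= 0)
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}
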