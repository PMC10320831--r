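# Synthetic multivariate activity patterns and BOLD-like time series with
# planted representational structure. These stand in for preprocessed ROI
# data: patterns are trial x unit matrices obtained by randomly mixing a
# source representation (e.g. a network layer's activations) plus Gaussian
# noise; time series are design regressors convolved with a canonical
# double-gamma HRF plus AR(1) noise sampled at the scanner TR.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with unit rate: a positive lobe
#' peaking at `peak` seconds and an undershoot peaking at `undershoot`
#' seconds scaled by `ratio`, normalized to maximum 1.
#'
#' @param t Time points (s).
#' @param peak Time-to-peak of the positive lobe (default 6 s).
#' @param undershoot Time-to-peak of the undershoot (default 16 s).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak + 1, rate = 1) -
                ratio * stats::dgamma(tt, shape = undershoot + 1, rate = 1))
  h / hmax
}

#' Convolve an event regressor with the HRF
#'
#' Builds an impulse train of `values` at `onsets` on a fine grid
#' (`dt` s), convolves with the double-gamma HRF, and samples at volume
#' times `(0:(n_vol-1)) * TR`.
#'
#' @param onsets Event onset times (s).
#' @param values Event amplitudes (parametric modulation); recycled.
#' @param n_vol Number of volumes.
#' @param TR Repetition time (s), default 1.6.
#' @param dt Convolution grid step (s).
#' @param durations Event durations (s); 0 gives impulses, > 0 boxcars.
#' @param hrf List of HRF parameters passed to [hrf_double_gamma()].
#' @return Numeric vector of length `n_vol`.
#' @export
convolve_events <- function(onsets, values = 1, n_vol, TR = 1.6, dt = 0.1,
                            durations = 0, hrf = list()) {
  run_len <- n_vol * TR + 32
  ng <- ceiling(run_len / dt)
  values <- rep_len(values, length(onsets))
  durations <- rep_len(durations, length(onsets))
  x <- numeric(ng)
  for (i in seq_along(onsets)) {
    if (onsets[i] < 0) stop("negative onset", call. = FALSE)
    i0 <- floor(onsets[i] / dt) + 1L
    i1 <- max(i0, floor((onsets[i] + durations[i]) / dt))
    idx <- i0:min(i1, ng)
    x[idx] <- x[idx] + values[i]
  }
  kt <- seq(0, 32, by = dt)
  k <- do.call(hrf_double_gamma, c(list(t = kt), hrf))
  xp <- c(numeric(length(k) - 1L), x)
  conv <- stats::filter(xp, k, method = "convolution", sides = 1)
  conv <- as.numeric(conv[length(k):length(xp)])
  vol_t <- (seq_len(n_vol) - 1L) * TR
  conv[pmin(floor(vol_t / dt) + 1L, length(conv))]
}

#' Synthesize multivariate patterns and BOLD-like time series
#'
#' Patterns: each subject's trial x unit matrix is an affine random
#' mixing of the source representation plus i.i.d. Gaussian noise
#' (`patterns = source %*% A_s + noise_sd * N`). Time series: the supplied
#' regressors (onsets + amplitudes) are convolved with the double-gamma
#' HRF at TR = 1.6 s and summed with planted betas, plus AR(1) noise.
#'
#' @param source Trial x feature source matrix (e.g. a network layer's
#'   activations) for pattern synthesis, or `NULL` for pure-noise
#'   patterns (`n_trials` then required).
#' @param generator List of options: `n_subjects` (default 1), `n_units`
#'   (default 30), `noise_sd` (default 1), `regressors` (data frame with
#'   `onset` and one amplitude column per regressor), `betas` (planted
#'   amplitudes, one per regressor column), `TR` (default 1.6),
#'   `n_vol`, `ar_phi` (default 0.3), `ts_noise_sd` (default 1), `hrf`
#'   (list for [hrf_double_gamma()]), `n_trials`.
#' @param seed Integer seed.
#' @return List of class `synthetic_neural` with `patterns` (list per
#'   subject), `timeseries` (list per subject), and `ground_truth`.
#' @export
simulate_neural <- function(source = NULL, generator = list(), seed = 1L) {
  g <- utils::modifyList(list(n_subjects = 1L, n_units = 30L, noise_sd = 1,
                              regressors = NULL, betas = NULL, TR = 1.6,
                              n_vol = NULL, ar_phi = 0.3, ts_noise_sd = 1,
                              hrf = list(), n_trials = NULL), generator)
  if (g$noise_sd < 0 || g$ts_noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  with_seed(derive_seed(seed, "neural"), function() {
    patterns <- NULL
    if (!is.null(source) || !is.null(g$n_trials)) {
      if (is.null(source)) {
        src <- matrix(0, g$n_trials, g$n_units)
        A <- diag(g$n_units)
      } else {
        src <- as.matrix(source)
        src <- apply(src, 2, zscore)
        src <- src[, apply(src, 2, stats::sd) > 1e-12, drop = FALSE]
        A <- NULL
      }
      patterns <- lapply(seq_len(g$n_subjects), function(s) {
        d <- ncol(src)
        Ai <- if (!is.null(A)) A
        else if (g$n_units > d + 1L) {
          # random semi-orthogonal mixing, orthogonal to the constant
          # vector: preserves the source's inner-product geometry exactly
          # when noise_sd = 0
          Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(g$n_units * d),
                                       g$n_units, d))))
          t(Q[, 2:(d + 1L), drop = FALSE])
        } else {
          matrix(stats::rnorm(d * g$n_units, 0, 1 / sqrt(d)), d, g$n_units)
        }
        src %*% Ai + matrix(stats::rnorm(nrow(src) * g$n_units, 0, g$noise_sd),
                            nrow(src), g$n_units)
      })
    }
    timeseries <- NULL
    if (!is.null(g$regressors)) {
      reg <- g$regressors
      stopifnot("onset" %in% names(reg))
      amp_cols <- setdiff(names(reg), "onset")
      betas <- g$betas %||% rep(1, length(amp_cols))
      n_vol <- g$n_vol %||% ceiling((max(reg$onset) + 24) / g$TR)
      X <- sapply(amp_cols, function(cc)
        convolve_events(reg$onset, reg[[cc]], n_vol = n_vol, TR = g$TR, hrf = g$hrf))
      timeseries <- lapply(seq_len(g$n_subjects), function(s) {
        e <- stats::rnorm(n_vol, 0, g$ts_noise_sd)
        if (g$ar_phi != 0) e <- as.numeric(stats::filter(e, g$ar_phi, method = "recursive"))
        as.numeric(X %*% betas) + e
      })
    }
    structure(list(patterns = patterns, timeseries = timeseries,
                   ground_truth = g, seed = as.integer(seed)),
              class = "synthetic_neural")
  })
}
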