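# ROI beta time courses, leave-one-subject-out peak statistics, PPI design
# construction, and the JZS Bayes factor for one-sample tests.

dv_chosen_minus_unchosen <- function(dv, choice) {
  ifelse(choice == 1, dv[, 2] - dv[, 1], dv[, 1] - dv[, 2])
}

# decision values under a model with the bonus channel manipulated:
# set_bon overrides the bonus value, set_cond the condition flag
dv_with <- function(model, params, data, stage, set_bon = NULL, set_cond = NULL) {
  d <- data
  if (!is.null(set_bon)) d$Bon <- rep_len(set_bon, d$n)
  if (!is.null(set_cond)) d$Cond <- rep_len(set_cond, d$n)
  model_dv(model, params, d, stage)
}

#' Build a univariate GLM design for ROI/BOLD analysis
#'
#' Constructs the named event regressors of the four ROI designs and
#' convolves them with the double-gamma HRF:
#' * GLM 3: `dv_env` (stage-1 DV difference, chosen minus unchosen),
#'   `dv_item` (stage-2), plus nuisance regressors `bonus`,
#'   `chosen_env_value`, `resp_left`, `resp_right`.
#' * GLM 4: the DV difference split into `dv_basic` (all information
#'   except the bonus), `dv_linked_bonus` (bonus contribution, linked
#'   blocks only), and `dv_unlinked_bonus` (bonus contribution computed
#'   as if linked, unlinked blocks only), at the onsets of `stage`.
#' * GLM 5: GLM 4 plus `first_trial` (first item trial of the block = 1,
#'   else -1) and `first_x_dv_linked_bonus` (stage 2).
#' * GLM 6: `dv` plus `salience` (sum of the options' absolute expected
#'   values) and `dv_sum`; salience and DV sum use expected value rather
#'   than the model DV, whose normalization discards value signs.
#'
#' Parametric regressor values are mean-centered before convolution.
#'
#' @param dataset A `choice_dataset` with choices.
#' @param subject Which subject's run to build the design for (each
#'   subject is one run on its own time axis); default the first.
#' @param glm Design number (3-6).
#' @param model,params Decision model supplying DVs (required for GLMs
#'   3-5; defaults to the expected-value model).
#' @param stage Stage whose onsets GLMs 4-6 are locked to.
#' @param TR Repetition time (s).
#' @param n_vol Number of volumes (default: covers the last onset + 24 s).
#' @param hrf HRF parameter list for [hrf_double_gamma()].
#' @return List of class `design_spec`: `events` (per-regressor onsets
#'   and mean-centered values), `X` (n_vol x regressor convolved design),
#'   `trial_values` (trial-level regressor data frame for epoched
#'   time-course fits), `onsets`, `TR`, `glm`.
#' @export
build_design <- function(dataset, glm = 3L, model = "ev", params = NULL,
                         stage = 1L, subject = NULL, TR = 1.6, n_vol = NULL,
                         hrf = list()) {
  stopifnot(inherits(dataset, "choice_dataset"), glm %in% 3:6)
  if (glm %in% 3:5 && is.null(model))
    stop("GLMs 3-5 require a decision model for the DV regressors", call. = FALSE)
  if (is.null(subject)) subject <- dataset$trials$subject[1]
  sub <- dataset
  sub$trials <- dataset$trials[dataset$trials$subject == subject, , drop = FALSE]
  dataset <- sub
  d1 <- model_data(dataset, 1L)
  d2 <- model_data(dataset, 2L)
  ev_of <- function(d) {
    n <- d$n
    pm <- matrix(sapply(1:2, function(k) rowMeans(matrix(d$P[, , k], nrow = n))), nrow = n)
    d$Mag * pm
  }
  events <- list()
  if (glm == 3L) {
    dv1 <- dv_chosen_minus_unchosen(model_dv(model, params, d1, 1L), d1$choice)
    dv2 <- dv_chosen_minus_unchosen(model_dv(model, params, d2, 2L), d2$choice)
    ev1 <- ev_of(d1)
    chosen_ev <- ifelse(d1$choice == 1, ev1[, 2], ev1[, 1])
    events <- list(
      dv_env = list(onset = d1$onset, value = dv1),
      dv_item = list(onset = d2$onset, value = dv2),
      bonus = list(onset = d1$onset, value = d1$Bon),
      chosen_env_value = list(onset = d1$onset + 2, value = chosen_ev),
      resp_left = list(onset = d1$onset[d1$choice == 0], value = 1, duration = 0.5),
      resp_right = list(onset = d1$onset[d1$choice == 1], value = 1, duration = 0.5))
    trial_values <- data.frame(dv_env = dv1, bonus = d1$Bon, chosen_env_value = chosen_ev)
    onsets <- d1$onset
  } else if (glm %in% c(4L, 5L)) {
    d <- if (stage == 1L) d1 else d2
    dv_full <- model_dv(model, params, d, stage)
    dv_basic <- dv_with(model, params, d, stage, set_bon = 0)
    bonus_part <- dv_with(model, params, d, stage, set_cond = 1) -
      dv_with(model, params, d, stage, set_bon = 0, set_cond = 1)
    db <- dv_chosen_minus_unchosen(dv_basic, d$choice)
    dbon <- dv_chosen_minus_unchosen(bonus_part, d$choice)
    trial_values <- data.frame(
      dv_basic = db,
      dv_linked_bonus = ifelse(d$Cond == 1, dbon, 0),
      dv_unlinked_bonus = ifelse(d$Cond == 0, dbon, 0))
    if (glm == 5L) {
      if (stage != 2L) stop("GLM5 is a stage-2 design", call. = FALSE)
      first <- ifelse(dataset$trials$trial[dataset$trials$stage == 2] == 1, 1, -1)
      trial_values$first_trial <- first
      trial_values$first_x_dv_linked_bonus <- first * trial_values$dv_linked_bonus
    }
    events <- lapply(trial_values, function(v) list(onset = d$onset, value = v))
    onsets <- d$onset
  } else {
    d <- if (stage == 1L) d1 else d2
    dv <- dv_chosen_minus_unchosen(model_dv(model, params, d, stage), d$choice)
    ev <- ev_of(d)
    trial_values <- data.frame(dv = dv,
                               salience = abs(ev[, 1]) + abs(ev[, 2]),
                               dv_sum = ev[, 1] + ev[, 2])
    events <- lapply(trial_values, function(v) list(onset = d$onset, value = v))
    onsets <- d$onset
  }
  if (is.null(n_vol))
    n_vol <- ceiling((max(vapply(events, function(e) max(e$onset), numeric(1))) + 24) / TR)
  n_vol <- as.integer(n_vol)
  X <- sapply(names(events), function(nm) {
    e <- events[[nm]]
    v <- e$value
    if (length(unique(v)) > 2L || !all(v %in% c(0, 1))) v <- v - mean(v)
    convolve_events(e$onset, v, n_vol = n_vol, TR = TR,
                    durations = e$duration %||% 0, hrf = hrf)
  })
  structure(list(events = events, X = X, trial_values = trial_values,
                 onsets = onsets, TR = TR, n_vol = n_vol, glm = as.integer(glm)),
            class = "design_spec")
}

#' Epoched ROI beta time courses
#'
#' For each subject, the ROI series is cubic-spline upsampled tenfold,
#' epochs are cut around each trial onset, and at every peristimulus
#' timepoint the ROI activity across trials is regressed (OLS, with
#' intercept) on the trial-level regressor values, yielding a beta time
#' course per regressor. Group mean and SEM are attached.
#'
#' @param series List of per-subject ROI series (volumes, sampled at
#'   `TR`), or a single numeric vector.
#' @param onsets Trial onset times (s), shared across subjects.
#' @param values Data frame of trial-level regressor values (one row per
#'   trial).
#' @param TR Repetition time (s).
#' @param window Peristimulus window in seconds, default `c(-2, 14)`.
#' @param upsample Upsampling factor (default 10; time step TR/10).
#' @return A `beta_timecourse`: `beta` array (subject x regressor x
#'   timepoint), `time` axis, `mean` and `sem` matrices.
#' @export
beta_timecourse <- function(series, onsets, values, TR = 1.6,
                            window = c(-2, 14), upsample = 10L) {
  if (is.numeric(series)) series <- list(series)
  if (length(series) < 2L) warning("group SEM requires >= 2 subjects", call. = FALSE)
  values <- as.data.frame(values)
  nt <- length(onsets)
  stopifnot(nrow(values) == nt)
  dt <- TR / upsample
  tax <- seq(window[1], window[2], by = dt)
  ns <- length(series)
  nr <- ncol(values)
  beta <- array(NA_real_, c(ns, nr, length(tax)),
                dimnames = list(NULL, names(values), NULL))
  X <- cbind(1, as.matrix(values))
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e) MASS_ginv(crossprod(X)))
  H <- XtXi %*% t(X)
  shortest <- (min(lengths(series)) - 1) * TR
  if (max(onsets) + window[2] > shortest)
    warning("epochs extend past run end; truncated samples held at last value",
            call. = FALSE)
  for (s in seq_len(ns)) {
    y <- series[[s]]
    vol_t <- (seq_along(y) - 1) * TR
    up <- stats::spline(vol_t, y, xout = seq(0, max(vol_t), by = dt))
    run_end <- max(up$x)
    for (ti in seq_along(tax)) {
      samp_t <- pmin(pmax(onsets + tax[ti], 0), run_end)
      yy <- up$y[round(samp_t / dt) + 1]
      b <- H %*% yy
      beta[s, , ti] <- b[-1]
    }
  }
  mn <- apply(beta, c(2, 3), mean)
  se <- apply(beta, c(2, 3), function(v) stats::sd(v) / sqrt(length(v)))
  structure(list(beta = beta, time = tax, mean = mn, sem = se, TR = TR,
                 upsample = upsample),
            class = "beta_timecourse")
}

# minimal pseudo-inverse fallback for rank-deficient trial designs
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Leave-one-subject-out peak statistics for a beta time course
#'
#' The group-mean curve defines a peak (largest absolute extremum after
#' time zero) and its full-width-half-maximum window. For each subject,
#' the peak position is located on the group curve recomputed without
#' that subject (within the FWHM window), and the subject's own beta at
#' that position is extracted, avoiding selection bias. Extracted peaks
#' are then tested against zero with a one-sample t and a JZS Bayes
#' factor.
#'
#' @param tc A [beta_timecourse()].
#' @param regressor Regressor name or index.
#' @param rule Peak-position rule within the window: `"heldout"`
#'   (position of the held-out group curve's extremum; default) or
#'   `"own"` (the subject's own extremum).
#' @return A `peak_stat` list: per-subject peaks and times, peak window,
#'   `t`, `df`, `p`, `bf10`.
#' @export
loso_peak <- function(tc, regressor, rule = c("heldout", "own")) {
  rule <- match.arg(rule)
  b <- tc$beta[, regressor, , drop = TRUE]
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  ns <- nrow(b)
  if (ns < 3L) stop("leave-one-subject-out needs >= 3 subjects", call. = FALSE)
  tax <- tc$time
  post <- which(tax >= 0)
  grp <- colMeans(b)
  if (max(abs(grp[post])) < 1e-12) stop("flat group curve: no peak definable", call. = FALSE)
  ipk <- post[which.max(abs(grp[post]))]
  sgn <- sign(grp[ipk])
  half <- abs(grp[ipk]) / 2
  inwin <- abs(grp) >= half & sign(grp) == sgn
  lo <- ipk; while (lo > 1 && inwin[lo - 1]) lo <- lo - 1
  hi <- ipk; while (hi < length(tax) && inwin[hi + 1]) hi <- hi + 1
  win <- lo:hi
  peaks <- times <- numeric(ns)
  for (s in seq_len(ns)) {
    ref <- if (rule == "heldout") colMeans(b[-s, , drop = FALSE]) else b[s, ]
    j <- win[which.max(sgn * ref[win])]
    peaks[s] <- b[s, j]
    times[s] <- tax[j]
  }
  tt <- stats::t.test(peaks)
  structure(list(peaks = peaks, peak_times = times,
                 group_peak_time = tax[ipk], window = range(tax[win]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, bf10 = bf_ttest(peaks)$bf10, rule = rule),
            class = "peak_stat")
}

#' Psychophysiological-interaction design
#'
#' Five columns: the psychological stage regressor (1 = environment
#' choice, 0 = item choice), two physiological ROI series, and the
#' stage-by-physiological interactions (physiological series are
#' mean-centered before multiplication). A constant stage regressor makes
#' the interactions collinear with the physiological columns and is
#' flagged.
#'
#' @param stage Psychological indicator per timepoint (1/0).
#' @param phys1,phys2 Physiological series of the two coupled regions.
#' @return Matrix with columns `stage`, `phys1`, `phys2`,
#'   `stage_x_phys1`, `stage_x_phys2`; attribute `collinear` flags a
#'   degenerate psychological regressor.
#' @export
ppi_design <- function(stage, phys1, phys2) {
  stopifnot(length(stage) == length(phys1), length(phys1) == length(phys2))
  c1 <- phys1 - mean(phys1)
  c2 <- phys2 - mean(phys2)
  X <- cbind(stage = stage, phys1 = phys1, phys2 = phys2,
             stage_x_phys1 = stage * c1, stage_x_phys2 = stage * c2)
  collinear <- stats::sd(stage) < 1e-12
  if (collinear)
    warning("constant stage regressor: interactions are collinear with the physiological columns",
            call. = FALSE)
  attr(X, "collinear") <- collinear
  X
}

#' One-sample t-test with JZS Bayes factor
#'
#' Frequentist one-sample t plus the Jeffreys-Zellner-Siow Bayes factor
#' (Cauchy prior on the standardized effect, scale `rscale`), computed by
#' numerical integration of the JZS marginal likelihood.
#'
#' @param values Sample values.
#' @param mu Null value (default 0).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return List with `t`, `df`, `p`, `bf10`.
#' @export
bf_ttest <- function(values, mu = 0, rscale = sqrt(2) / 2) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  tt <- stats::t.test(values, mu = mu)
  t <- unname(tt$statistic)
  nu <- n - 1
  # marginal likelihood under the alternative: integrate over the
  # inverse-gamma mixture representation of the Cauchy prior
  f <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      rscale / sqrt(2 * pi) * g^(-3 / 2) * exp(-rscale^2 / (2 * g))
  }
  num <- stats::integrate(f, 0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  list(t = t, df = nu, p = tt$p.value, bf10 = num / den)
}
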