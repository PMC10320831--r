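# HRF convolution, GLM designs, epoched beta time courses, LOSO peaks,
# PPI design, and the JZS Bayes factor.

test_that("a unit impulse convolves to the HRF kernel itself", {
  x <- convolve_events(0, 1, n_vol = 20, TR = 1.6)
  k <- hrf_double_gamma((0:19) * 1.6)
  expect_equal(x, k, tolerance = 0.02)
  expect_equal(max(hrf_double_gamma(seq(0, 30, by = 0.01))), 1, tolerance = 1e-3)
  expect_error(convolve_events(-3, 1, n_vol = 10), "negative onset")
})

test_that("the ROI GLM designs carry exactly the documented regressors", {
  ds <- small_dataset(n1 = 30, n2 = 30, n_subjects = 2, seed = 301)
  d3 <- build_design(ds, glm = 3, model = "ev")
  expect_identical(colnames(d3$X),
                   c("dv_env", "dv_item", "bonus", "chosen_env_value",
                     "resp_left", "resp_right"))
  d4 <- build_design(ds, glm = 4, model = "ev", stage = 1)
  expect_identical(names(d4$trial_values),
                   c("dv_basic", "dv_linked_bonus", "dv_unlinked_bonus"))
  d5 <- build_design(ds, glm = 5, model = "ev", stage = 2)
  expect_identical(names(d5$trial_values),
                   c("dv_basic", "dv_linked_bonus", "dv_unlinked_bonus",
                     "first_trial", "first_x_dv_linked_bonus"))
  expect_error(build_design(ds, glm = 5, model = "ev", stage = 1), "stage-2")
  d6 <- build_design(ds, glm = 6, stage = 1)
  expect_identical(names(d6$trial_values), c("dv", "salience", "dv_sum"))
  expect_identical(nrow(d3$X), d3$n_vol)
})

test_that("a zero-bonus dataset has identically zero bonus-split regressors", {
  ds <- small_dataset(n1 = 25, n2 = 0, n_subjects = 2, seed = 311)
  for (b in seq_along(ds$task$blocks)) ds$task$blocks[[b]]$bonus <- 0
  ds$trials$bonus <- 0
  d4 <- build_design(ds, glm = 4, model = "ev", stage = 1)
  expect_true(all(d4$trial_values$dv_linked_bonus == 0))
  expect_true(all(d4$trial_values$dv_unlinked_bonus == 0))
  expect_false(all(d4$trial_values$dv_basic == 0))
})

test_that("beta time courses recover planted amplitudes and vanish without signal", {
  set.seed(12)
  onsets <- seq(8, 600, by = 16)
  vals <- rnorm(length(onsets))
  # noiseless: peak beta equals the planted amplitude at the HRF peak
  syn <- simulate_neural(generator = list(
    n_subjects = 2, regressors = data.frame(onset = onsets, dv = vals),
    betas = 0.8, ts_noise_sd = 0, ar_phi = 0), seed = 31)
  tc <- beta_timecourse(syn$timeseries, onsets, data.frame(dv = vals))
  expect_equal(max(tc$mean["dv", ]), 0.8, tolerance = 0.01)
  expect_equal(tc$time[which.max(tc$mean["dv", ])], 6, tolerance = 0.5)
  expect_equal(diff(tc$time)[1], 0.16, tolerance = 1e-12) # TR / 10 axis
  # constant series: every slope beta exactly zero
  tc0 <- beta_timecourse(list(rep(2, 400), rep(5, 400)), onsets,
                         data.frame(dv = vals))
  expect_true(all(abs(tc0$beta) < 1e-9))
  # pure noise: group betas stay near zero at the would-be peak
  syn0 <- simulate_neural(generator = list(
    n_subjects = 8, regressors = data.frame(onset = onsets, dv = vals),
    betas = 0, ts_noise_sd = 1), seed = 32)
  tcn <- beta_timecourse(syn0$timeseries, onsets, data.frame(dv = vals))
  tstat <- tcn$mean["dv", ] / tcn$sem["dv", ]
  expect_lt(abs(tstat[which.min(abs(tcn$time - 6))]), 4)
})

test_that("epochs past the run end are truncated with a warning", {
  expect_warning(
    beta_timecourse(list(rnorm(20), rnorm(20)), onsets = c(5, 25),
                    values = data.frame(v = c(1, -1)), TR = 1.6),
    "truncated")
})

test_that("LOSO peak extraction finds a planted bump and rejects flat curves", {
  tax <- seq(-2, 14, by = 0.16)
  bump <- exp(-(tax - 6)^2 / 2)
  ns <- 6
  beta <- array(NA_real_, c(ns, 1, length(tax)), dimnames = list(NULL, "dv", NULL))
  for (s in 1:ns) beta[s, 1, ] <- bump * (0.8 + 0.1 * s / ns)
  tc <- structure(list(beta = beta, time = tax,
                       mean = matrix(colMeans(beta[, 1, ]), 1,
                                     dimnames = list("dv")),
                       sem = NULL, TR = 1.6, upsample = 10),
                  class = "beta_timecourse")
  pk <- loso_peak(tc, "dv")
  expect_true(all(pk$peak_times == 6)) # identical curves peak at the center
  expect_gt(pk$t, 10)
  expect_identical(pk$df, ns - 1L)
  # sign flip: peaks negate, |t| unchanged
  tcneg <- tc; tcneg$beta <- -tcneg$beta
  pkn <- loso_peak(tcneg, "dv")
  expect_equal(pkn$peaks, -pk$peaks)
  expect_equal(abs(pkn$t), abs(pk$t), tolerance = 1e-9)
  # flat curves have no definable peak
  tc0 <- tc; tc0$beta[] <- 0
  expect_error(loso_peak(tc0, "dv"), "flat")
  expect_error(loso_peak(structure(list(beta = beta[1:2, , , drop = FALSE],
                                        time = tax), class = "beta_timecourse"),
                         "dv"), ">= 3")
})

test_that("the PPI design has five columns and flags degenerate psychology", {
  set.seed(13)
  n <- 120
  stage <- rep(c(1, 0), each = n / 2)
  p1 <- rnorm(n); p2 <- rnorm(n)
  X <- ppi_design(stage, p1, p2)
  expect_identical(colnames(X),
                   c("stage", "phys1", "phys2", "stage_x_phys1", "stage_x_phys2"))
  expect_false(attr(X, "collinear"))
  expect_warning(ppi_design(rep(1, n), p1, p2), "collinear")
  # planted stage-dependent coupling recovers its sign
  y <- 0.5 * p1 + 0.8 * stage * (p1 - mean(p1)) + rnorm(n, 0, 0.3)
  b <- coef(lm(y ~ X))
  expect_gt(b["Xstage_x_phys1"], 0)
})

test_that("the JZS Bayes factor favors the null at t = 0 and grows with evidence", {
  null_vals <- c(-2, -1, 1, 2) # mean exactly zero
  for (nv in list(null_vals, rep(c(-1, 1), 12))) {
    bt <- bf_ttest(nv)
    expect_equal(bt$t, 0, tolerance = 1e-12)
    expect_lt(bt$bf10, 1)
  }
  set.seed(14)
  base <- rnorm(24)
  base <- (base - mean(base)) / sd(base)
  bfs <- vapply(seq(0, 1.5, by = 0.25),
                function(d) bf_ttest(base + d)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0)) # monotone in |t| at fixed n
  expect_gt(bfs[5], 10) # d = 1 at n = 24 is strong evidence
  # symmetric in the sign of the effect
  expect_equal(bf_ttest(base + 0.5)$bf10, bf_ttest(-base - 0.5)$bf10,
               tolerance = 1e-6)
})
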