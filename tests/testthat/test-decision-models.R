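# The model zoo: convolution, network forward passes, parametric decision
# values, cross-validated fitting, and model comparison.

brute_convolve <- function(X, W, b) {
  I <- nrow(X); J <- ncol(X); M <- nrow(W); N <- ncol(W)
  out <- matrix(NA_real_, I - M + 1, J - N + 1)
  for (i in seq_len(I - M + 1)) for (j in seq_len(J - N + 1)) {
    acc <- b
    for (m in seq_len(M)) for (n in seq_len(N))
      acc <- acc + W[m, n] * X[i + m - 1, j + n - 1]
    out[i, j] <- acc
  }
  out
}

test_that("convolution matches a nested-loop oracle over all small shapes", {
  set.seed(42)
  for (I in 1:6) for (J in 1:3) for (M in 1:I) for (N in 1:J) {
    X <- matrix(rnorm(I * J), I, J)
    W <- matrix(rnorm(M * N), M, N)
    b <- rnorm(1)
    expect_equal(convolve_map(X, W, b), brute_convolve(X, W, b), tolerance = 1e-12)
  }
  # known hand case: column [1,2,3] with [1,-1] kernel
  expect_equal(convolve_map(matrix(1:3), matrix(c(1, -1)), 0),
               matrix(c(-1, -1)))
  # degenerate detector: all-zero weights give a constant map
  expect_equal(convolve_map(matrix(rnorm(12), 4, 3), matrix(0, 2, 2), 7),
               matrix(7, 3, 2))
  expect_identical(dim(convolve_map(matrix(0, 20, 2), matrix(0, 2, 1), 0)),
                   c(19L, 2L))
  expect_error(convolve_map(matrix(0, 2, 2), matrix(0, 3, 1), 0), "larger")
})

test_that("network forward pass matches hand-computed arithmetic on a toy block", {
  blk <- toy_block(c(0.2, 0.6, 0.9), c(0.5, 0.1, 0.4), mag_l = 2, mag_r = -1,
                   bonus = 1.5, cond = "linked")
  task <- task_from_blocks(list(blk))
  config <- net_config("cnn", n_detectors = 1, detector_shape = c(2, 1),
                       n_hidden = 2, standardize = FALSE, symmetric = FALSE)
  params <- net_init(config, q = 3, seed = 1)
  params$W1 <- matrix(c(1, -0.5)); params$b1 <- 0.1
  d <- nrow(params$W2)
  expect_identical(d, 2L * 2L * 2L + 4L) # maps + mags + mag-maps + bon + cond
  params$W2 <- matrix(seq(0.1, by = 0.05, length.out = d * 2), d, 2)
  params$b2 <- c(0.2, -0.1)
  params$W3 <- matrix(c(1, -1, 0.5, 0.25), 2, 2)
  params$b3 <- c(0.05, -0.05)
  fw <- net_forward(params, task)
  # hand computation with explicit loops
  pl <- c(0.2, 0.6, 0.9); pr <- c(0.5, 0.1, 0.4)
  fml <- 0.1 + 1 * pl[1:2] - 0.5 * pl[2:3]
  fmr <- 0.1 + 1 * pr[1:2] - 0.5 * pr[2:3]
  concat <- c(fml, fmr, 2, -1, fml * 2, fmr * -1, 1.5, 1)
  y <- pmax(as.numeric(t(params$W2) %*% concat) + params$b2, 0)
  dv <- as.numeric(t(params$W3) %*% y) + params$b3
  expect_equal(as.numeric(fw$concat), concat, tolerance = 1e-12)
  expect_equal(as.numeric(fw$dv), dv, tolerance = 1e-12)
  expect_equal(as.numeric(fw$p), exp(dv) / sum(exp(dv)), tolerance = 1e-12)
  # the label-equivariant variant averages this pass with the swapped pass
  params$config$symmetric <- TRUE
  concat_sw <- c(fmr, fml, -1, 2, fmr * -1, fml * 2, 1.5, 1)
  y_sw <- pmax(as.numeric(t(params$W2) %*% concat_sw) + params$b2, 0)
  dv_sw <- as.numeric(t(params$W3) %*% y_sw) + params$b3
  expect_equal(as.numeric(net_forward(params, task)$dv),
               (dv + dv_sw[2:1]) / 2, tolerance = 1e-12)
})

test_that("softmax probabilities are symmetric, shift-invariant, and normalized", {
  expect_equal(as.numeric(softmax2(c(1.3, 1.3))), c(0.5, 0.5))
  dv <- matrix(rnorm(20), 10, 2)
  expect_equal(softmax2(dv), softmax2(dv + 5.7), tolerance = 1e-12)
  p <- softmax2(dv * 100)
  expect_true(all(p > 0) && all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("identical options yield indifference in every model", {
  blk <- toy_block(rep(0.5, 20), rep(0.5, 20), mag_l = 3, mag_r = 3)
  task <- task_from_blocks(list(blk))
  for (m in c("ev", "mvs", "power", "cpt")) {
    par <- switch(m, ev = NULL, mvs = c(1, 1, rep(0.5, 6)),
                  power = c(2, rep(0.5, 6)), cpt = c(0.8, 0.9, 2, 0.7, 0.8, rep(0.5, 6)))
    expect_equal(as.numeric(model_prob(m, par, task)), c(0.5, 0.5),
                 tolerance = 1e-12, label = m)
  }
})

test_that("subjective-value models reduce to expected value at identity parameters", {
  task <- small_task(n1 = 25, n2 = 0, seed = 121)
  betas <- c(0.7, 1.2, 0.3, -0.4, 0.9, 0.6)
  cptv <- cpt_dv(c(1, 1, 1, 1, 1, betas), task)
  mvsv <- mvs_dv(c(0, 0, betas), task)
  powv <- power_dv(c(1, betas), task)
  expect_equal(cptv, mvsv, tolerance = 1e-12)
  expect_equal(powv, mvsv, tolerance = 1e-12)
  # and the probability contract agrees with the logistic DV-GLM when the
  # (softmax-cancelling) bonus/condition main effects are zero
  b2 <- betas; b2[3:4] <- 0
  p_two_dv <- softmax2(mvs_dv(c(0, 0, b2), task))
  p_glm <- softmax2(glm_dv(c(0, b2[1], b2[2], 0, 0, b2[5], b2[6]), task))
  expect_equal(p_two_dv, p_glm, tolerance = 1e-10)
})

test_that("probability weighting matches direct arithmetic and preserves endpoints", {
  for (g in c(0.4, 0.61, 1, 1.3)) {
    expect_equal(cpt_weight(0, g), 0)
    expect_equal(cpt_weight(1, g), 1)
  }
  expect_equal(cpt_weight(0.1, 0.61), 0.1863025664, tolerance = 1e-9)
  # subjective probability examples with known moments
  expect_equal(unname(mvs_dv(c(1, 0, 0, 1, 0, 0, 0, 0),
                             task_from_blocks(list(toy_block(
                               c(rep(0.2, 10), rep(0.8, 10)),
                               rep(0.5, 20)))))[1, 1]),
               0.59, tolerance = 1e-12) # 0.5 + 1 * 0.09
  expect_equal(unname(power_dv(c(2, 0, 1, 0, 0, 0, 0),
                               task_from_blocks(list(toy_block(
                                 c(0.2, 0.8), c(0.2, 0.8)))))[1, 1]),
               0.34, tolerance = 1e-12) # (0.04 + 0.64) / 2
  # g -> 0+ limit: positive probabilities transduce to 1
  expect_equal(unname(power_dv(c(1e-9, 0, 1, 0, 0, 0, 0),
                               task_from_blocks(list(toy_block(
                                 c(0.3, 0.9), c(0.3, 0.9)))))[1, 1]),
               1, tolerance = 1e-6)
})

test_that("autoencoder forward pass follows the sigmoid-readout arithmetic", {
  task <- small_task(n1 = 10, n2 = 0, seed = 131)
  d <- envchoice:::model_data(task, 1L)
  zerop <- list(W4 = matrix(0, 3, 10), b4 = rep(0, 3),
                W5 = matrix(0, 2, 3), b5 = c(0.7, -0.2))
  dv <- autoencoder_dv(zerop, d)
  expect_true(all(abs(dv[, 1] - 0.7) < 1e-12) && all(abs(dv[, 2] + 0.2) < 1e-12))
  # hand toy: one input row through a 2-node sigmoid layer
  p <- list(W4 = matrix(rnorm(20), 2, 10), b4 = c(0.1, -0.3),
            W5 = matrix(rnorm(4), 2, 2), b5 = c(0, 0))
  X <- envchoice:::autoencoder_features(d)
  z <- 1 / (1 + exp(-(p$W4 %*% X[1, ] + p$b4)))
  expect_equal(as.numeric(autoencoder_dv(p, d)[1, ]),
               as.numeric(p$W5 %*% z), tolerance = 1e-12)
})

test_that("simplified moment-input variants reproduce the moment operator", {
  task <- small_task(n1 = 15, n2 = 0, seed = 141)
  d <- envchoice:::model_data(task, 1L)
  cfg <- net_config("cnn_mean_var_skew", n_hidden = 4, standardize = FALSE)
  params <- net_init(cfg, q = 20, seed = 1)
  feats <- envchoice:::dense_features(params, d)
  for (i in c(1, 7)) {
    ml <- moments(d$P[i, , 1]); mr <- moments(d$P[i, , 2])
    expect_equal(unname(feats[i, 1:6]),
                 c(ml$mean, mr$mean, ml$variance, mr$variance,
                   ml$skewness, mr$skewness), tolerance = 1e-12)
  }
  expect_identical(ncol(feats), 16L) # 3 moments x 2 options, doubled by mag, + 4
  cfgm <- net_config("cnn_mean", n_hidden = 4, standardize = FALSE)
  expect_identical(ncol(envchoice:::dense_features(net_init(cfgm, 20, 1), d)), 8L)
})

test_that("item-choice network is indifferent between identical items", {
  blk <- toy_block(0.5, 0.5, mag_l = 1, mag_r = 1)
  ds <- list(stage = 2L, n = 1L, q = 1L, P = array(0.4, c(1, 1, 2)),
             Mag = matrix(2, 1, 2), Bon = 0.3, Cond = 1, choice = NA)
  params <- net_init(net_config("ann", n_hidden = 6, standardize = FALSE), q = 1, seed = 3)
  fw <- net_forward(params, ds)
  expect_equal(as.numeric(fw$p), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("cross-validation folds partition the trials reproducibly", {
  ds <- small_dataset(n1 = 40, n2 = 0, n_subjects = 2, seed = 151)
  f1 <- fit_model("glm", ds, folds = 8, seed = 9, control = list(refit_full = FALSE))
  f2 <- fit_model("glm", ds, folds = 8, seed = 9, control = list(refit_full = FALSE))
  expect_identical(f1$fold_of, f2$fold_of)
  expect_identical(sort(unique(f1$fold_of)), 1:8)
  expect_identical(length(f1$fold_of), 80L)
  expect_true(all(table(f1$fold_of) == 10))
  expect_false(any(is.na(f1$trial_prob))) # every trial scored exactly once
  expect_equal(f1$fold_nll_mean, f2$fold_nll_mean, tolerance = 1e-12)
  expect_true(all(f1$fold_nll_sum >= 0))
})

test_that("network training reduces the training objective", {
  ds <- small_dataset(n1 = 40, n2 = 0, n_subjects = 2, seed = 161,
                      agent = agent_spec("ev", temperature = 1))
  par <- train_net(ds, net_config("cnn", n_hidden = 8), seed = 2, epochs = 120)
  h <- attr(par, "nll_history")
  expect_lt(tail(h, 1), h[1] * 0.8)
  expect_lt(max(diff(h)), 0.02) # monotone up to small adaptive-step upticks
})

test_that("random choices drive held-out likelihood to the entropy floor", {
  ds <- small_dataset(n1 = 100, n2 = 100, n_subjects = 5, seed = 171)
  ds$trials$choice <- with_seed_local(9, function() rbinom(nrow(ds$trials), 1, 0.5))
  f <- fit_model("glm", ds, folds = 5, seed = 3, control = list(refit_full = FALSE))
  expect_lt(abs(mean(f$fold_nll_mean) - log(2)), 0.05)
  expect_lt(abs(f$accuracy - 0.5), 0.1)
})

test_that("model comparison reports pooled-variance t-tests with the right df", {
  ds <- small_dataset(n1 = 40, n2 = 0, n_subjects = 2, seed = 181)
  fa <- fit_model("glm", ds, folds = 20, seed = 5, control = list(refit_full = FALSE))
  fb <- fit_model("ev", ds, folds = 20, seed = 5, control = list(refit_full = FALSE))
  cmp <- compare_models(list(fa, fb))
  expect_identical(cmp$df["glm", "ev"], 38) # 20 + 20 - 2
  expect_identical(nrow(cmp$table), 2L)
  # identical fold NLLs: t = 0, p = 1
  cmp0 <- compare_models(list(fa, fa))
  expect_equal(cmp0$t[1, 2], 0)
  expect_equal(cmp0$p[1, 2], 1)
})

test_that("planted parametric preferences win the likelihood comparison", {
  task <- generate_task(task_config(n_stage1 = 150, n_stage2 = 0), seed = 191)
  ag <- agent_spec("cpt", c(0.6, 0.6, 2.5, 0.5, 0.5, 0.8, 6, 0, 0, 0.4, 0.3),
                   temperature = 1)
  ds <- simulate_agent(task, ag, n_subjects = 8, seed = 192)
  fcpt <- fit_model("cpt", ds, folds = 5, seed = 7,
                    control = list(restarts = 3, refit_full = FALSE))
  fev <- fit_model("ev", ds, folds = 5, seed = 7, control = list(refit_full = FALSE))
  expect_lt(mean(fcpt$fold_nll_mean), mean(fev$fold_nll_mean))
})

test_that("model fits round-trip through the JSON container", {
  ds <- small_dataset(n1 = 30, n2 = 0, n_subjects = 2, seed = 351)
  for (m in c("mvs", "cnn")) {
    ctl <- list(restarts = 2)
    if (m == "cnn") ctl <- list(config = net_config("cnn", n_hidden = 4), epochs = 40)
    fit <- fit_model(m, ds, folds = 3, seed = 5, control = ctl)
    p <- tempfile(fileext = ".json")
    write_model_fit(fit, p)
    back <- read_model_fit(p)
    expect_equal(back$fold_nll_mean, fit$fold_nll_mean, tolerance = 1e-12)
    d1 <- envchoice:::model_data(ds, 1L)
    expect_equal(model_dv(m, back$full, d1), model_dv(m, fit$full, d1),
                 tolerance = 1e-10, label = m)
  }
})
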