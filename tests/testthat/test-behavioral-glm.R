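# Statistical moments and the GLM1/GLM2 choice regressions.

test_that("population moments match hand-derived values", {
  m <- moments(c(rep(0.2, 10), rep(0.8, 10)))
  expect_equal(m$mean, 0.5)
  expect_equal(m$variance, 0.09)
  expect_equal(m$skewness, 0)
  const <- moments(rep(0.4, 20))
  expect_equal(const$variance, 0)
  expect_equal(const$skewness, 0) # degenerate case by convention
  p <- c(0.1, 0.2, 0.2, 0.9)
  a <- moments(p); b <- moments(1 - p)
  expect_equal(a$variance, b$variance)
  expect_equal(a$skewness, -b$skewness) # mirrored distributions
})

test_that("per-subject logistic fits attain the reference-optimizer likelihood", {
  ds <- small_dataset(n1 = 60, n2 = 0, n_subjects = 2, seed = 61,
                      agent = agent_spec("ev", temperature = 3))
  data <- envchoice:::model_data(ds, 1L)
  X <- as.matrix(envchoice:::glm1_regressors(data))
  for (s in 1:2) {
    idx <- data$subject == s
    Xi <- cbind(1, apply(X[idx, ], 2, scale))
    y <- data$choice[idx]
    nll <- function(b) {
      eta <- Xi %*% b
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
    }
    ref <- stats::optim(rep(0, ncol(Xi)), nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    fit <- fit_glm1(ds)
    got <- nll(fit$coefficients[s, ])
    expect_lt(abs(got - ref$value), 1e-4)
    expect_lte(ref$value, got + 1e-4)
  }
})

test_that("recoding the chosen side negates every coefficient", {
  ds <- small_dataset(n1 = 80, n2 = 80, n_subjects = 3, seed = 71,
                      agent = agent_spec("ev", temperature = 3))
  flipped <- ds
  flipped$trials$choice <- 1 - flipped$trials$choice
  for (stg in 1:2) {
    a <- fit_glm1(ds, stage = stg)
    b <- fit_glm1(flipped, stage = stg)
    expect_equal(unname(b$coefficients), unname(-a$coefficients), tolerance = 1e-6)
  }
})

test_that("planted value sensitivity is recovered and absent effects stay null", {
  task <- generate_task(task_config(), seed = 81)
  # strong EV sensitivity (2.0): direction and significance are robust even
  # where choices approach determinism (near-separated subjects excluded)
  strong <- agent_spec("glm", c(0, 0, 0, 0, 0, 2, 0), temperature = 1)
  g_strong <- suppressWarnings(
    fit_glm1(simulate_agent(task, strong, n_subjects = 24, seed = 82)))
  expect_gt(g_strong$group["ev_rl", "mean"], 0)
  expect_lt(g_strong$group["ev_rl", "p"], 0.001)
  # softer planted coefficient: recovered on the raw scale within 2 SE
  ag <- agent_spec("glm", c(0, 0, 0, 0, 0, 0.6, 0), temperature = 1)
  ds <- simulate_agent(task, ag, n_subjects = 24, seed = 83)
  g <- fit_glm1(ds, stage = 1, standardize = FALSE)
  ev <- g$group["ev_rl", ]
  se <- ev$mean / ev$t # SE of the group mean
  expect_lt(abs(ev$mean - 0.6), 2 * se)
  expect_lt(ev$p, 0.001)
  expect_identical(ev$df, g$n_subjects - 1)
  # bonus was ignored by the generating agent: three-way interaction covers 0
  expect_gt(g$group["prob_bon_cond", "p"], 0.01)
})

test_that("moment preferences are recovered by the moment regression", {
  task <- generate_task(task_config(), seed = 91)
  seeker <- agent_spec("mvs", c(5, 0, 0, 3, 0, 0, 1, 0), temperature = 1)
  g <- fit_glm2(simulate_agent(task, seeker, n_subjects = 16, seed = 92))
  expect_gt(g$group["variance_rl", "mean"], 0)
  expect_lt(g$group["variance_rl", "p"], 0.01)
  # a pure expected-value agent is exactly spanned by the EV regressor,
  # so moment effects must vanish
  neutral <- agent_spec("glm", c(0, 0, 0, 0, 0, 1.5, 0), temperature = 1)
  g0 <- fit_glm2(simulate_agent(task, neutral, n_subjects = 16, seed = 93))
  expect_gt(g0$group["variance_rl", "p"], 0.01)
  expect_gt(g0$group["skewness_rl", "p"], 0.01)
})

test_that("degenerate and separated data are flagged, not silently fit", {
  # identical options on every trial: no information in any regressor
  blk <- toy_block(seq(0.1, 0.9, length.out = 20), seq(0.1, 0.9, length.out = 20),
                   mag_l = 2, mag_r = 2)
  task <- task_from_blocks(rep(list(blk), 30))
  ds <- simulate_agent(task, agent_spec("ev", temperature = 1), n_subjects = 3, seed = 7)
  expect_error(fit_glm1(ds), "identifiable|separation|no-information")
  # near-deterministic agent: perfect separation flagged with warning
  ds2 <- small_dataset(n1 = 50, n2 = 0, n_subjects = 3, seed = 101,
                       agent = agent_spec("ev", temperature = 1e-6))
  expect_warning(try(fit_glm1(ds2), silent = TRUE), "excluded|separation")
})

test_that("group tests require at least two subjects", {
  ds <- small_dataset(n1 = 30, n2 = 0, n_subjects = 1, seed = 111)
  expect_error(fit_glm1(ds), "2 subjects")
})
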