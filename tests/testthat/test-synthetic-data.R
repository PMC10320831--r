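# Task generation, agent simulation, and synthetic neural data.

test_that("default design realizes the printed task constants exactly", {
  task <- generate_task(task_config(), seed = 5)
  expect_length(task$blocks, 200)
  nit <- vapply(task$blocks, `[[`, integer(1), "n_item_trials")
  expect_identical(sum(nit), 200L)
  expect_true(all(nit >= 0 & nit <= 3))
  # 400 distinct environments
  all_envs <- unlist(lapply(task$blocks, function(b)
    list(b$env_left, b$env_right)), recursive = FALSE)
  expect_length(all_envs, 400)
  expect_identical(anyDuplicated(vapply(all_envs, function(e)
    paste(signif(e$item_probs, 10), collapse = ","), character(1))), 0L)
  # exact valence-pair counts: 53.5 / 31.5 / 15 % of 200
  vp <- table(vapply(task$blocks, `[[`, character(1), "valence_pair"))
  expect_identical(as.integer(vp[c("gain", "loss", "mixed")]), c(107L, 63L, 30L))
  # exact linked/unlinked split
  bc <- table(vapply(task$blocks, `[[`, character(1), "bonus_condition"))
  expect_identical(as.integer(bc[c("linked", "unlinked")]), c(100L, 100L))
})

test_that("environments respect ranges, valence signs, and displayed means", {
  task <- generate_task(task_config(), seed = 9)
  for (b in task$blocks) {
    for (e in list(b$env_left, b$env_right)) {
      expect_length(e$item_probs, 20)
      expect_true(all(e$item_probs >= 0 & e$item_probs <= 1))
      expect_true(all(abs(e$item_mags) <= 10 + 1e-12))
      expect_equal(e$mean_mag, mean(e$item_mags), tolerance = 1e-12)
      if (e$valence == "gain") expect_gte(e$mean_mag, 0) else expect_lt(e$mean_mag, 0)
    }
    expect_true(b$bonus >= -4 && b$bonus <= 6)
    if (b$n_item_trials > 0) {
      idx <- unlist(b$item_pairs)
      expect_true(all(idx >= 1 & idx <= 20))
      expect_identical(anyDuplicated(idx), 0L) # without replacement in block
    }
  }
})

test_that("generation is deterministic in the seed and honors empty/invalid configs", {
  a <- generate_task(task_config(n_stage1 = 30, n_stage2 = 30), seed = 3)
  b <- generate_task(task_config(n_stage1 = 30, n_stage2 = 30), seed = 3)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_task(task_config(n_stage1 = 30, n_stage2 = 30), seed = 4)
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
  empty <- generate_task(task_config(n_stage1 = 0, n_stage2 = 0), seed = 1)
  expect_length(empty$blocks, 0)
  expect_error(task_config(valence_mix = c(gain = 0.9, loss = 0.2, mixed = -0.1)))
  expect_error(task_config(prob_shape_range = c(-1, 2)))
  expect_error(task_config(n_stage1 = 10, n_stage2 = 100))
})

test_that("configured ranges hold across random configurations (property)", {
  for (s in 1:5) {
    cfg <- with_seed_local(s, function() task_config(
      n_stage1 = sample(10:40, 1), n_stage2 = sample(10:30, 1),
      n_items = sample(c(10L, 20L), 1),
      bonus_range = sort(runif(2, -5, 7)),
      mean_mag_range = sort(runif(2, 0.5, 8)),
      mag_limit = 9))
    task <- generate_task(cfg, seed = 100 + s)
    for (b in task$blocks) {
      expect_true(b$bonus >= cfg$bonus_range[1] && b$bonus <= cfg$bonus_range[2])
      for (e in list(b$env_left, b$env_right)) {
        expect_true(all(e$item_probs >= 0 & e$item_probs <= 1))
        expect_true(all(abs(e$item_mags) <= cfg$mag_limit + 1e-12))
      }
    }
    nit <- vapply(task$blocks, `[[`, integer(1), "n_item_trials")
    expect_identical(sum(nit), cfg$n_stage2)
  }
})

test_that("stage-2 offers always come from the chosen stage-1 environment", {
  ds <- small_dataset(n1 = 60, n2 = 60, n_subjects = 3, seed = 21)
  tr <- ds$trials
  for (i in which(tr$stage == 2)) {
    row <- tr[i, ]
    ch <- tr$choice[tr$stage == 1 & tr$subject == row$subject & tr$block == row$block]
    blk <- ds$task$blocks[[row$block]]
    env <- if (ch == 1) blk$env_right else blk$env_left
    expect_identical(row$prob_left, env$item_probs[row$item_left])
    expect_identical(row$mag_right, env$item_mags[row$item_right])
  }
})

test_that("agent choice converges to greedy and indifferent softmax limits", {
  task <- small_task(n1 = 50, n2 = 0, seed = 31)
  d1 <- envchoice:::model_data(task, 1L)
  ev <- glm_dv(c(0, 0, 0, 0, 0, 1, 0), d1)[, 2]
  greedy <- simulate_agent(task, agent_spec("ev", temperature = 1e-8), 1, seed = 2)
  expect_identical(greedy$trials$choice[greedy$trials$stage == 1],
                   as.numeric(ev > 0))
  indiff <- simulate_agent(task, agent_spec("ev", temperature = 1e8), 40, seed = 2)
  pr <- mean(indiff$trials$choice[indiff$trials$stage == 1])
  expect_lt(abs(pr - 0.5), 3 * sqrt(0.25 / 2000)) # binomial error bound
})

test_that("simulated choice rates match the analytic softmax probabilities", {
  task <- small_task(n1 = 20, n2 = 0, seed = 41)
  ag <- agent_spec("ev", temperature = 2)
  d1 <- envchoice:::model_data(task, 1L)
  p_analytic <- model_prob("ev", NULL, d1, temperature = 2)[, 2]
  ds <- simulate_agent(task, ag, n_subjects = 300, seed = 5)
  emp <- tapply(ds$trials$choice[ds$trials$stage == 1],
                ds$trials$block[ds$trials$stage == 1], mean)
  mc_se <- sqrt(p_analytic * (1 - p_analytic) / 300)
  expect_true(all(abs(emp - p_analytic) < 4 * pmax(mc_se, 0.01)))
})

test_that("noiseless planted patterns reproduce the source representation", {
  src <- with_seed_local(77, function() matrix(rnorm(20 * 6), 20, 6))
  syn <- simulate_neural(src, list(n_subjects = 2, n_units = 120, noise_sd = 0),
                         seed = 3)
  rho <- rdm_similarity(compute_rdm(syn$patterns[[1]]),
                        compute_rdm(apply(src, 2, function(x) (x - mean(x)) / sd(x))))
  expect_gt(rho, 0.9)
  expect_error(simulate_neural(src, list(noise_sd = -1), seed = 1), "noise")
})

test_that("datasets round-trip through the CSV + JSON serialization", {
  ds <- small_dataset(n1 = 10, n2 = 10, n_subjects = 2, seed = 51)
  stem <- file.path(tempdir(), "rt")
  write_dataset(ds, stem)
  back <- read_dataset(stem)
  expect_equal(back$trials$choice, ds$trials$choice)
  expect_equal(back$task$blocks[[3]]$env_left$item_probs,
               ds$task$blocks[[3]]$env_left$item_probs, tolerance = 1e-12)
  expect_identical(back$n_subjects, 2L)
})
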