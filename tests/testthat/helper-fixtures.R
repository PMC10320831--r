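# Shared fixtures, built in code at test time.

small_task <- function(n1 = 40, n2 = 40, seed = 11) {
  generate_task(task_config(n_stage1 = n1, n_stage2 = n2), seed = seed)
}

small_dataset <- function(n1 = 40, n2 = 40, n_subjects = 2, seed = 11,
                          agent = agent_spec("ev", temperature = 1)) {
  simulate_agent(small_task(n1, n2, seed), agent,
                 n_subjects = n_subjects, seed = seed + 1)
}

# a toy block with arbitrary item counts for hand-computed forward passes
toy_block <- function(probs_l, probs_r, mag_l = 2, mag_r = 3,
                      bonus = 1, cond = "linked") {
  mk <- function(p, m) structure(
    list(item_probs = p, item_mags = rep(m, length(p)), mean_mag = m,
         valence = if (m >= 0) "gain" else "loss"), class = "environment")
  list(block = 1L, env_left = mk(probs_l, mag_l), env_right = mk(probs_r, mag_r),
       bonus = bonus, bonus_condition = cond, n_item_trials = 0L,
       item_pairs = NULL, onset_stage1 = 5, onsets_stage2 = numeric(0))
}

task_from_blocks <- function(blocks, config = task_config()) {
  structure(list(blocks = blocks, config = config, seed = 0L),
            class = "task_design")
}

# Hand-wired convolutional network with an explicit nonlinear moment
# preference: detector 1 is a local average (value signal, scaled by
# magnitude), detector 2 a local contrast whose absolute sum (a
# dispersion measure) is assembled in the hidden layer via paired ReLU
# units. DV_k = a * sum(mag-scaled detector-1 map, option k) / L
#             + cc * sum |detector-2 map|, option k) / L.
variance_sensitive_cnn <- function(q = 20, a = 1, cc = 2) {
  L <- q - 1
  H <- 4 * L + 4 # |contrast| pairs for both options + value pairs
  config <- net_config("cnn", n_detectors = 2, n_hidden = H, standardize = FALSE)
  params <- net_init(config, q = q, seed = 1)
  params$W1 <- cbind(c(0.5, 0.5), c(1, -1))
  params$b1 <- c(0, 0)
  d <- nrow(params$W2)
  W2 <- matrix(0, d, H); b2 <- rep(0, H)
  # concat layout: fm1 (2L), fm2 (2L), mags (2), mag*fm1 (2L), mag*fm2 (2L),
  # bonus, cond
  off_fm2 <- 2 * L
  off_magfm1 <- 4 * L + 2
  h <- 0
  for (k in 1:2) {
    for (i in seq_len(L)) {
      col <- off_fm2 + (k - 1) * L + i
      W2[col, h + 1] <- 1; W2[col, h + 2] <- -1 # ReLU pair -> |fm2|
      h <- h + 2
    }
  }
  val_units <- integer(2)
  for (k in 1:2) {
    cols <- off_magfm1 + (k - 1) * L + seq_len(L)
    W2[cols, h + 1] <- 1; W2[cols, h + 2] <- -1 # ReLU pair -> signed value
    val_units[k] <- h + 1
    h <- h + 2
  }
  W3 <- matrix(0, H, 2)
  for (k in 1:2) {
    idx <- (k - 1) * 2 * L + seq_len(2 * L)
    W3[idx, k] <- cc / L
    W3[val_units[k], k] <- a / L
    W3[val_units[k] + 1, k] <- -a / L
  }
  params$W2 <- W2; params$b2 <- b2
  params$W3 <- W3; params$b3 <- c(0, 0)
  params
}

# deterministic trial-level pattern source with planted structure
planted_patterns <- function(source, n_subjects, noise_sd, seed) {
  simulate_neural(source, list(n_subjects = n_subjects, n_units = 24,
                               noise_sd = noise_sd), seed = seed)$patterns
}

with_seed_local <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}
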