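# Two-stage task generation. A block is one environment-choice (stage 1)
# trial followed by 0-3 item-choice (stage 2) trials whose items are drawn
# from whichever environment ends up chosen. Environments are bundles of 20
# probabilistic items displayed as probability bars plus one mean-magnitude
# number.

#' Task generation configuration
#'
#' Defaults reproduce the study design: 200 stage-1 trials (400 distinct
#' environments), 200 stage-2 trials, environments of 20 items, a
#' gain/gain : loss/loss : mixed valence mix of 53.5/31.5/15%, a block
#' bonus drawn uniformly from \[-4, 6\], a 50/50 linked/unlinked bonus
#' condition split, and item magnitudes within \[-10, 10\].
#'
#' Item probabilities are drawn from a Beta distribution (the bar heights);
#' item magnitudes are drawn as bounded deviations around a target mean so
#' that the displayed mean magnitude is exact. Gain environments have
#' non-negative magnitudes, loss environments non-positive ones.
#'
#' @param n_stage1 Number of stage-1 (environment choice) trials.
#' @param n_stage2 Total number of stage-2 (item choice) trials.
#' @param n_items Items per environment.
#' @param valence_mix Named proportions for `gain`, `loss`, `mixed` blocks.
#' @param prob_shape_range Range from which each environment's two Beta
#'   shape parameters are drawn (independently, uniformly), so that
#'   environments differ in the location, spread, and skew of their item
#'   probability distributions -- the dimensions environment choice is
#'   about.
#' @param mag_limit Absolute bound on item magnitudes (currency units).
#' @param mean_mag_range Range of the displayed mean magnitude (its sign is
#'   set by the environment's valence).
#' @param bonus_range Range of the block bonus.
#' @param linked_ratio Proportion of blocks in the linked bonus condition.
#' @param max_item_trials Maximum stage-2 trials per block.
#' @param iti_range Range (s) of the inter-trial interval used to lay trial
#'   onsets on a continuous time axis for BOLD-like simulation.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_stage1 = 200L, n_stage2 = 200L, n_items = 20L,
                        valence_mix = c(gain = 0.535, loss = 0.315, mixed = 0.15),
                        prob_shape_range = c(0.6, 6),
                        mag_limit = 10, mean_mag_range = c(1, 8),
                        bonus_range = c(-4, 6), linked_ratio = 0.5,
                        max_item_trials = 3L, iti_range = c(4, 8)) {
  if (any(valence_mix < 0) || abs(sum(valence_mix) - 1) > 1e-9)
    stop("valence_mix must be non-negative and sum to 1", call. = FALSE)
  if (any(prob_shape_range <= 0) || diff(prob_shape_range) < 0)
    stop("Beta shape range must be positive and increasing", call. = FALSE)
  if (mag_limit <= 0 || any(mean_mag_range < 0) || diff(mean_mag_range) < 0 ||
      mean_mag_range[2] > mag_limit)
    stop("invalid magnitude ranges", call. = FALSE)
  if (diff(bonus_range) < 0) stop("invalid bonus_range", call. = FALSE)
  if (linked_ratio < 0 || linked_ratio > 1)
    stop("linked_ratio must lie in [0, 1]", call. = FALSE)
  if (n_stage2 > n_stage1 * max_item_trials)
    stop("n_stage2 exceeds n_stage1 * max_item_trials", call. = FALSE)
  if (n_items < 2 * max_item_trials)
    stop("n_items must allow drawing item pairs without replacement", call. = FALSE)
  structure(list(
    n_stage1 = as.integer(n_stage1), n_stage2 = as.integer(n_stage2),
    n_items = as.integer(n_items), valence_mix = valence_mix,
    prob_shape_range = prob_shape_range,
    mag_limit = mag_limit, mean_mag_range = mean_mag_range,
    bonus_range = bonus_range, linked_ratio = linked_ratio,
    max_item_trials = as.integer(max_item_trials), iti_range = iti_range
  ), class = "task_config")
}

# one environment: probabilities Beta(a, b) with the shapes themselves
# drawn per environment (environments differ in distributional shape);
# magnitudes are a target mean
# plus mean-zero uniform deviations, rescaled if needed so every item stays
# inside [0, mag_limit] (gain) or [-mag_limit, 0] (loss). The displayed
# mean therefore equals mean(item_mags) exactly.
generate_environment <- function(valence, config) {
  n <- config$n_items
  sh <- stats::runif(2, config$prob_shape_range[1], config$prob_shape_range[2])
  probs <- stats::rbeta(n, sh[1], sh[2])
  m <- stats::runif(1, config$mean_mag_range[1], config$mean_mag_range[2])
  dev <- stats::runif(n, -config$mag_limit / 2, config$mag_limit / 2)
  dev <- dev - mean(dev)
  lo <- 0; hi <- config$mag_limit
  room <- min(m - lo, hi - m)
  mx <- max(abs(dev))
  if (mx > room) dev <- dev * room / mx
  mags <- m + dev
  if (valence == "loss") { mags <- -mags; m <- -m }
  structure(list(item_probs = probs, item_mags = mags,
                 mean_mag = mean(mags), valence = valence),
            class = "environment")
}

#' Generate a two-stage task design
#'
#' Builds the full block structure deterministically from a seed. The
#' valence mix and linked/unlinked split are realized by deterministic
#' allocation (floor counts plus largest-remainder assignment, then a
#' seeded shuffle over blocks), so the realized proportions are exact
#' counts, not Bernoulli expectations. Stage-2 trial counts per block are
#' drawn uniformly on `0:max_item_trials` and then repaired by seeded
#' single-step adjustments until they sum to `n_stage2`. Item pairs for
#' stage-2 trials are index pairs into the (eventually) chosen
#' environment, drawn without replacement within a block.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed always yields an identical
#'   design.
#' @return A list of class `task_design` with elements `blocks` (list of
#'   blocks, each holding `env_left`, `env_right`, `bonus`,
#'   `bonus_condition`, `n_item_trials`, `item_pairs`, onset times),
#'   `config` and `seed`.
#' @export
generate_task <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_stage1
  if (n == 0L) {
    return(structure(list(blocks = list(), config = config, seed = as.integer(seed)),
                     class = "task_design"))
  }
  with_seed(derive_seed(seed, "task"), function() {
    vcnt <- allocate_counts(n, config$valence_mix)
    vlab <- sample(rep(c("gain", "loss", "mixed"), vcnt))
    lcnt <- allocate_counts(n, c(config$linked_ratio, 1 - config$linked_ratio))
    cond <- sample(rep(c("linked", "unlinked"), lcnt))

    nit <- sample(0:config$max_item_trials, n, replace = TRUE)
    while (sum(nit) != config$n_stage2) {
      i <- sample.int(n, 1)
      if (sum(nit) > config$n_stage2 && nit[i] > 0) nit[i] <- nit[i] - 1L
      if (sum(nit) < config$n_stage2 && nit[i] < config$max_item_trials) nit[i] <- nit[i] + 1L
    }

    t0 <- 0
    blocks <- vector("list", n)
    for (b in seq_len(n)) {
      val <- switch(vlab[b],
        gain  = c("gain", "gain"),
        loss  = c("loss", "loss"),
        mixed = sample(c("gain", "loss"))
      )
      env_l <- generate_environment(val[1], config)
      env_r <- generate_environment(val[2], config)
      bonus <- stats::runif(1, config$bonus_range[1], config$bonus_range[2])
      k <- nit[b]
      pairs <- NULL
      if (k > 0) {
        idx <- sample.int(config$n_items, 2L * k)
        pairs <- lapply(seq_len(k), function(j) idx[c(2L * j - 1L, 2L * j)])
      }
      onset1 <- t0 + stats::runif(1, config$iti_range[1], config$iti_range[2])
      onsets2 <- numeric(0)
      t <- onset1
      if (k > 0) {
        for (j in seq_len(k)) {
          t <- t + stats::runif(1, config$iti_range[1], config$iti_range[2])
          onsets2 <- c(onsets2, t)
        }
      }
      t0 <- t + 2
      blocks[[b]] <- list(
        block = b, env_left = env_l, env_right = env_r,
        valence_pair = vlab[b], bonus = bonus, bonus_condition = cond[b],
        n_item_trials = as.integer(k), item_pairs = pairs,
        onset_stage1 = onset1, onsets_stage2 = onsets2
      )
    }
    structure(list(blocks = blocks, config = config, seed = as.integer(seed)),
              class = "task_design")
  })
}

#' @export
print.task_design <- function(x, ...) {
  n2 <- sum(vapply(x$blocks, function(b) b$n_item_trials, integer(1)))
  cat(sprintf("task_design: %d stage-1 blocks, %d stage-2 trials, seed %d\n",
              length(x$blocks), n2, x$seed))
  invisible(x)
}

# flat per-block summary used by serialization and the design checks
task_block_table <- function(task) {
  do.call(rbind, lapply(task$blocks, function(b) {
    data.frame(block = b$block, valence_pair = b$valence_pair,
               bonus = b$bonus, bonus_condition = b$bonus_condition,
               n_item_trials = b$n_item_trials,
               mean_mag_left = b$env_left$mean_mag,
               mean_mag_right = b$env_right$mean_mag,
               onset_stage1 = b$onset_stage1)
  }))
}

#' Serialize a task design or choice dataset to CSV + JSON sidecar
#'
#' Writes `<stem>_trials.csv` (one row per trial, wide columns holding the
#' full per-item probabilities and magnitudes of both options),
#' `<stem>_envs.csv` (one row per environment) and `<stem>.json` (config,
#' seed, and column dictionary). [read_dataset()] reads the same dialect,
#' which is also the accepted format for externally supplied behavioral
#' tables.
#'
#' @param x A `choice_dataset` (from [simulate_agent()]) or `task_design`.
#' @param stem Path stem (without extension).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(x, stem) {
  if (inherits(x, "task_design")) x <- list(trials = NULL, task = x)
  task <- x$task
  envs <- do.call(rbind, lapply(task$blocks, function(b) {
    rbind(
      data.frame(block = b$block, side = "left",
                 valence = b$env_left$valence, mean_mag = b$env_left$mean_mag,
                 t(stats::setNames(b$env_left$item_probs, sprintf("p%02d", seq_along(b$env_left$item_probs)))),
                 t(stats::setNames(b$env_left$item_mags, sprintf("m%02d", seq_along(b$env_left$item_mags))))),
      data.frame(block = b$block, side = "right",
                 valence = b$env_right$valence, mean_mag = b$env_right$mean_mag,
                 t(stats::setNames(b$env_right$item_probs, sprintf("p%02d", seq_along(b$env_right$item_probs)))),
                 t(stats::setNames(b$env_right$item_mags, sprintf("m%02d", seq_along(b$env_right$item_mags)))))
    )
  }))
  paths <- c(envs = paste0(stem, "_envs.csv"), json = paste0(stem, ".json"))
  utils::write.csv(envs, paths[["envs"]], row.names = FALSE)
  if (!is.null(x$trials)) {
    paths <- c(paths, trials = paste0(stem, "_trials.csv"))
    utils::write.csv(x$trials, paths[["trials"]], row.names = FALSE)
  }
  side <- list(config = unclass(task$config), seed = task$seed,
               n_subjects = if (!is.null(x$n_subjects)) x$n_subjects else 0L,
               agent = if (!is.null(x$agent)) x$agent[c("model", "temperature")] else NULL,
               columns = list(
                 trials = "subject, block, stage, trial (within block), onset (s), bonus, cond (1 linked / 0 unlinked), choice (1 right / 0 left), stage-2 item prob/mag per side",
                 envs = "block, side, valence, mean_mag, p01..pNN item probabilities, m01..mNN item magnitudes"))
  jsonlite::write_json(side, paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a serialized choice dataset
#'
#' @param stem Path stem used in [write_dataset()].
#' @return A `choice_dataset` list (without agent parameters).
#' @export
read_dataset <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  envs <- utils::read.csv(paste0(stem, "_envs.csv"), stringsAsFactors = FALSE)
  pcols <- grep("^p[0-9]+$", names(envs), value = TRUE)
  mcols <- grep("^m[0-9]+$", names(envs), value = TRUE)
  blocks <- lapply(sort(unique(envs$block)), function(b) {
    rows <- envs[envs$block == b, ]
    mk <- function(side) {
      r <- rows[rows$side == side, ]
      structure(list(item_probs = as.numeric(r[1, pcols]),
                     item_mags = as.numeric(r[1, mcols]),
                     mean_mag = r$mean_mag[1], valence = r$valence[1]),
                class = "environment")
    }
    list(block = b, env_left = mk("left"), env_right = mk("right"))
  })
  trials_path <- paste0(stem, "_trials.csv")
  trials <- if (file.exists(trials_path)) utils::read.csv(trials_path) else NULL
  structure(list(trials = trials,
                 task = structure(list(blocks = blocks, config = side$config,
                                       seed = side$seed), class = "task_design"),
                 n_subjects = side$n_subjects, agent = side$agent),
            class = "choice_dataset")
}
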