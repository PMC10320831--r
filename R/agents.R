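# Choice-making agents with known parameters. An agent is a registered
# decision model plus a softmax temperature; simulation resolves the task
# block by block so that stage-2 item offers always come from the
# environment the agent actually chose in stage 1.

#' Specify a simulated agent
#'
#' @param model Model identifier (see [model_ids()]).
#' @param params Model parameters (numeric vector for parametric models,
#'   structured parameters for networks; may be `NULL` for `"ev"`).
#' @param temperature Softmax temperature (> 0). Small values approach
#'   greedy choice of the higher-DV option; large values approach
#'   indifference.
#' @param stage2_model,stage2_params Model used for stage-2 item choices;
#'   defaults to an expected-value chooser at the same temperature.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(model = "ev", params = NULL, temperature = 1,
                       stage2_model = "ev", stage2_params = NULL) {
  if (!model %in% model_ids()) stop("unknown model id: ", model, call. = FALSE)
  if (!stage2_model %in% model_ids()) stop("unknown model id: ", stage2_model, call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(model = model, params = params, temperature = temperature,
                 stage2_model = stage2_model, stage2_params = stage2_params),
            class = "agent_spec")
}

#' Simulate agents performing the task
#'
#' Computes the agent's stage-1 choice probabilities from its model,
#' samples environment choices, resolves each block's pre-drawn item-index
#' pairs against the chosen environment, then samples stage-2 item
#' choices. Each simulated subject traverses the same task design with
#' independent choice noise.
#'
#' @param task A [generate_task()] design.
#' @param agent An [agent_spec()].
#' @param n_subjects Number of simulated subjects.
#' @param seed Integer seed.
#' @return A `choice_dataset`: list with `trials` (one row per trial:
#'   `subject`, `block`, `stage`, `trial`, `onset`, `bonus`, `cond`,
#'   stage-2 item features, `choice` with 1 = right), `task`, `agent`,
#'   `n_subjects`.
#' @export
simulate_agent <- function(task, agent, n_subjects = 1L, seed = 1L) {
  stopifnot(inherits(task, "task_design"), inherits(agent, "agent_spec"))
  d1 <- model_data(task, 1L)
  p1 <- model_prob(agent$model, agent$params, d1, stage = 1L,
                   temperature = agent$temperature)[, 2]
  nb <- length(task$blocks)
  nit <- vapply(task$blocks, `[[`, integer(1), "n_item_trials")
  rows_per_subj <- nb + sum(nit)
  N <- rows_per_subj * n_subjects
  col <- list(subject = integer(N), block = integer(N), stage = integer(N),
              trial = integer(N), onset = numeric(N), bonus = numeric(N),
              cond = numeric(N), prob_left = rep(NA_real_, N),
              mag_left = rep(NA_real_, N), prob_right = rep(NA_real_, N),
              mag_right = rep(NA_real_, N), item_left = rep(NA_integer_, N),
              item_right = rep(NA_integer_, N), choice = numeric(N))
  trials <- with_seed(derive_seed(seed, "agent"), function() {
    i <- 0L
    for (s in seq_len(n_subjects)) {
      ch1 <- as.numeric(stats::runif(nb) < p1)
      for (b in seq_len(nb)) {
        blk <- task$blocks[[b]]
        cnd <- as.numeric(blk$bonus_condition == "linked")
        i <- i + 1L
        col$subject[i] <- s; col$block[i] <- b; col$stage[i] <- 1L
        col$trial[i] <- 0L; col$onset[i] <- blk$onset_stage1
        col$bonus[i] <- blk$bonus; col$cond[i] <- cnd
        col$choice[i] <- ch1[b]
        if (blk$n_item_trials == 0L) next
        env <- if (ch1[b] == 1) blk$env_right else blk$env_left
        for (j in seq_len(blk$n_item_trials)) {
          pair <- blk$item_pairs[[j]]
          d2 <- list(stage = 2L, n = 1L, q = 1L,
                     P = array(env$item_probs[pair], c(1, 1, 2)),
                     Mag = matrix(env$item_mags[pair], 1, 2),
                     Bon = blk$bonus, Cond = cnd, choice = NA_real_)
          p2 <- model_prob(agent$stage2_model, agent$stage2_params, d2,
                           stage = 2L, temperature = agent$temperature)[, 2]
          i <- i + 1L
          col$subject[i] <- s; col$block[i] <- b; col$stage[i] <- 2L
          col$trial[i] <- j; col$onset[i] <- blk$onsets_stage2[j]
          col$bonus[i] <- blk$bonus; col$cond[i] <- cnd
          col$prob_left[i] <- env$item_probs[pair[1]]
          col$mag_left[i] <- env$item_mags[pair[1]]
          col$prob_right[i] <- env$item_probs[pair[2]]
          col$mag_right[i] <- env$item_mags[pair[2]]
          col$item_left[i] <- pair[1]; col$item_right[i] <- pair[2]
          col$choice[i] <- as.numeric(stats::runif(1) < p2)
        }
      }
    }
    as.data.frame(col)
  })
  structure(list(trials = trials, task = task,
                 agent = agent, n_subjects = as.integer(n_subjects)),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("choice_dataset: %d trials (%d stage-1, %d stage-2), %d subject(s)\n",
              nrow(x$trials), sum(x$trials$stage == 1), sum(x$trials$stage == 2),
              x$n_subjects))
  invisible(x)
}
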