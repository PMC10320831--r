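# End-to-end orchestration: simulate the task and an agent, run the
# behavioral GLMs, fit and compare decision models, decompose the
# network's decision value, run the representational analyses, and fit
# synthetic ROI time courses — all from one config, fully determined by
# its seed.

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param task A [task_config()].
#' @param agent An [agent_spec()] generating the choices.
#' @param n_subjects Simulated subjects.
#' @param models Model ids to fit and compare.
#' @param folds Cross-validation folds.
#' @param net Network size overrides (`n_hidden`, `epochs`) applied to
#'   network models; small defaults keep the demo pipeline fast.
#' @param rsa RSA settings: `n_perm`, `n_units`, `noise_sd`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, task = task_config(),
                       agent = agent_spec("mvs", c(0.5, 0, 1, 5, 0, 0, 1, 0.5),
                                          temperature = 1),
                       n_subjects = 8L,
                       models = c("cnn", "glm"), folds = 20L,
                       net = list(n_hidden = 32L, epochs = 250L),
                       rsa = list(n_perm = 500L, n_units = 30L, noise_sd = 1)) {
  structure(list(seed = as.integer(seed), task = task, agent = agent,
                 n_subjects = as.integer(n_subjects), models = models,
                 folds = as.integer(folds), net = net, rsa = rsa),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"), tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> behavioral GLMs -> cross-validated model fitting
#' and comparison -> partial-DV moment correlations -> RSA on synthetic
#' patterns -> ROI beta time course, writing every table under `outdir`
#' stamped with the seed and a config hash. A failure in any stage aborts
#' with an error naming the stage; artifacts already written are
#' retained.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  stamp <- function(df) { df$seed <- config$seed; df$config_hash <- hash; df }
  res <- list(seed = config$seed, hash = hash)

  res$dataset <- stage("simulate", {
    task <- generate_task(config$task, seed = config$seed)
    ds <- simulate_agent(task, config$agent, n_subjects = config$n_subjects,
                         seed = derive_seed(config$seed, "choices"))
    write_dataset(ds, file.path(outdir, "dataset"))
    ds
  })

  res$glm1 <- stage("behavioral_glm", {
    g1 <- fit_glm1(res$dataset, stage = 1L)
    g2 <- fit_glm2(res$dataset)
    utils::write.csv(stamp(cbind(coef = rownames(g1$group), g1$group)),
                     file.path(outdir, "glm1_group.csv"), row.names = FALSE)
    utils::write.csv(stamp(cbind(coef = rownames(g2$group), g2$group)),
                     file.path(outdir, "glm2_group.csv"), row.names = FALSE)
    list(glm1 = g1, glm2 = g2)
  })

  res$fits <- stage("fit_models", {
    lapply(config$models, function(m) {
      ctl <- list(epochs = config$net$epochs %||% 250L,
                  restarts = 5L)
      if (!m %in% names(parametric_registry()))
        ctl$config <- net_config(m, n_hidden = config$net$n_hidden %||% 32L)
      fit_model(m, res$dataset, stage = 1L, folds = config$folds,
                seed = derive_seed(config$seed, paste0("fit_", m)), control = ctl)
    })
  })

  res$comparison <- stage("compare", {
    cmp <- compare_models(res$fits)
    utils::write.csv(stamp(cmp$table), file.path(outdir, "model_comparison.csv"),
                     row.names = FALSE)
    cmp
  })

  cnn_idx <- which(vapply(res$fits, function(f) f$model, character(1)) == "cnn")
  if (length(cnn_idx) == 1L) {
    res$features <- stage("partial_dv", {
      tab <- partial_dv_table(res$fits[[cnn_idx]]$full, res$dataset)
      mc <- moment_correlations(tab)
      utils::write.csv(stamp(mc), file.path(outdir, "partial_dv_correlations.csv"),
                       row.names = FALSE)
      list(table = tab, correlations = mc)
    })

    res$rsa <- stage("rsa", {
      fw <- net_forward(res$fits[[cnn_idx]]$full, res$dataset)
      syn <- simulate_neural(fw$act$hidden,
                             generator = list(n_subjects = config$n_subjects,
                                              n_units = config$rsa$n_units %||% 30L,
                                              noise_sd = config$rsa$noise_sd %||% 1),
                             seed = derive_seed(config$seed, "patterns"))
      tab <- layerwise_rsa(res$fits[[cnn_idx]]$full, res$dataset, syn$patterns,
                           n_perm = config$rsa$n_perm %||% 500L,
                           seed = derive_seed(config$seed, "rsa"))
      utils::write.csv(stamp(tab), file.path(outdir, "rsa_layers.csv"),
                       row.names = FALSE)
      tab
    })
  }

  res$timecourse <- stage("timecourse", {
    des <- build_design(res$dataset, glm = 3L, model = "ev")
    onsets1 <- des$events$dv_env$onset
    syn <- simulate_neural(
      generator = list(n_subjects = config$n_subjects,
                       regressors = data.frame(onset = onsets1,
                                               dv = des$trial_values$dv_env),
                       betas = 1, n_vol = des$n_vol, ts_noise_sd = 0.5),
      seed = derive_seed(config$seed, "bold"))
    tc <- beta_timecourse(syn$timeseries, onsets1,
                          data.frame(dv_env = des$trial_values$dv_env))
    out <- data.frame(time = tc$time, beta = tc$mean["dv_env", ],
                      sem = tc$sem["dv_env", ])
    utils::write.csv(stamp(out), file.path(outdir, "timecourse_dv_env.csv"),
                     row.names = FALSE)
    tc
  })

  jsonlite::write_json(list(seed = config$seed, config_hash = hash,
                            finished = format(Sys.time())),
                       file.path(outdir, "run.json"), auto_unbox = TRUE)
  say("pipeline complete: ", outdir)
  invisible(res)
}

#' Write and read a pipeline configuration
#'
#' Round-trips a [run_config()] through JSON losslessly (parametric agent
#' specifications only; a network agent's weights belong in a model-fit
#' file, see [write_model_fit()]).
#'
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(config$agent$params, "net_params"))
    stop("network agents are serialized with write_model_fit(), not here",
         call. = FALSE)
  out <- rapply(unclass(config), unclass, how = "replace")
  out$task$valence_mix <- as.list(out$task$valence_mix) # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$task$valence_mix <- unlist(raw$task$valence_mix)
  cfg <- do.call(task_config, raw$task)
  ag <- do.call(agent_spec, lapply(raw$agent, function(x)
    if (is.list(x)) unlist(x) else x))
  run_config(seed = raw$seed, task = cfg, agent = ag,
             n_subjects = raw$n_subjects, models = raw$models,
             folds = raw$folds, net = raw$net, rsa = raw$rsa)
}
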