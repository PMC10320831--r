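# Parametric decision-value models and the model registry. Every model maps
# a trial's option features to a pair of decision values (DV_left,
# DV_right); choice probability is softmax(DV / temperature). The logistic
# decision-value GLM produces a single rightward DV, represented as the
# pair (0, DV_R) so that the two-option softmax reduces exactly to the
# logistic link.

# extract per-trial model inputs from a choice_dataset (or a bare
# task_design for simulation). Returns:
#   P    n x q x 2 item probability array (q = items per option; 1 in stage 2)
#   Mag  n x 2 option magnitudes (mean magnitude in stage 1, item magnitude
#        in stage 2)
#   Bon, Cond, choice (NA when not yet simulated), block, subject, onset
model_data <- function(dataset, stage = 1L) {
  if (inherits(dataset, "task_design")) {
    dataset <- structure(list(trials = NULL, task = dataset, n_subjects = 1L),
                         class = "choice_dataset")
  }
  task <- dataset$task
  q <- length(task$blocks[[1]]$env_left$item_probs)
  if (is.null(dataset$trials)) {
    stopifnot(stage == 1L)
    n <- length(task$blocks)
    P <- array(NA_real_, c(n, q, 2))
    Mag <- matrix(NA_real_, n, 2)
    for (b in seq_len(n)) {
      blk <- task$blocks[[b]]
      P[b, , 1] <- blk$env_left$item_probs; P[b, , 2] <- blk$env_right$item_probs
      Mag[b, ] <- c(blk$env_left$mean_mag, blk$env_right$mean_mag)
    }
    bon <- vapply(task$blocks, `[[`, numeric(1), "bonus")
    cond <- as.numeric(vapply(task$blocks, `[[`, character(1), "bonus_condition") == "linked")
    return(list(stage = 1L, n = n, q = q, P = P, Mag = Mag, Bon = bon, Cond = cond,
                choice = rep(NA_real_, n), block = seq_len(n),
                subject = rep(1L, n),
                onset = vapply(task$blocks, `[[`, numeric(1), "onset_stage1")))
  }
  tr <- dataset$trials[dataset$trials$stage == stage, , drop = FALSE]
  n <- nrow(tr)
  if (stage == 1L) {
    P <- array(NA_real_, c(n, q, 2))
    Mag <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      blk <- task$blocks[[tr$block[i]]]
      P[i, , 1] <- blk$env_left$item_probs; P[i, , 2] <- blk$env_right$item_probs
      Mag[i, ] <- c(blk$env_left$mean_mag, blk$env_right$mean_mag)
    }
  } else {
    P <- array(c(tr$prob_left, tr$prob_right), c(n, 1, 2))
    Mag <- cbind(tr$mag_left, tr$mag_right)
  }
  list(stage = as.integer(stage), n = n, q = dim(P)[2], P = P, Mag = Mag,
       Bon = tr$bonus, Cond = tr$cond, choice = tr$choice,
       block = tr$block, subject = tr$subject, onset = tr$onset)
}

# per-option population moments of the item probabilities
option_moments <- function(P) {
  n <- dim(P)[1]
  out <- list()
  for (nm in c("mean", "variance", "skewness")) out[[nm]] <- matrix(0, n, 2)
  for (k in 1:2) {
    M <- matrix(P[, , k], nrow = n)
    mu <- rowMeans(M)
    ce <- M - mu
    v <- rowMeans(ce^2)
    s <- ifelse(v < 1e-12, 0, rowMeans(ce^3) / pmax(v, 1e-12)^1.5)
    out$mean[, k] <- mu; out$variance[, k] <- v; out$skewness[, k] <- s
  }
  out
}

# DV_k = b1*maghat + b2*probhat + b3*Bon + b4*Cond + b5*(maghat*probhat)
#        + b6*(probhat*Bon*Cond), shared by MVS / power-law / CPT
dv_core <- function(beta, maghat, probhat, bon, cond) {
  # n x 2 matrices plus length-n vectors; vector terms recycle per column
  beta[1] * maghat + beta[2] * probhat + beta[5] * maghat * probhat +
    probhat * (beta[6] * bon * cond) + beta[3] * bon + beta[4] * cond
}

#' Mean-variance-skewness decision values
#'
#' The subjective probability of an option is the mean of its item
#' probabilities plus `rho` times their variance plus `sigma` times their
#' standardized skewness; decision values combine subjective probability
#' with magnitude, bonus and bonus-condition terms.
#'
#' @param par Named or positional vector `c(rho, sigma, b1..b6)`.
#' @param data A `model_data` list (internal) or `choice_dataset`.
#' @return n x 2 matrix of decision values (left, right).
#' @export
mvs_dv <- function(par, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  mom <- option_moments(data$P)
  probhat <- mom$mean + par[1] * mom$variance + par[2] * mom$skewness
  dv_core(par[3:8], data$Mag, probhat, data$Bon, data$Cond)
}

#' Power-law decision values
#'
#' Each item probability is transduced by a power `g` before averaging:
#' subjective probability is `mean(p^g)` over the option's items.
#'
#' @param par Vector `c(g, b1..b6)`.
#' @inheritParams mvs_dv
#' @return n x 2 matrix of decision values.
#' @export
power_dv <- function(par, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  n <- data$n
  probhat <- sapply(1:2, function(k) rowMeans(matrix(data$P[, , k]^par[1], nrow = n)))
  dv_core(par[2:7], data$Mag, matrix(probhat, nrow = n), data$Bon, data$Cond)
}

#' Cumulative-prospect-theory probability weighting function
#'
#' `w(p) = p^c / (p^c + (1-p)^c)^(1/c)`; `c` is the gain-domain curvature
#' `gamma` or the loss-domain curvature `delta`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param c Curvature parameter, `0 < c <= 1.5`.
#' @return Weighted probabilities; `w(0) = 0`, `w(1) = 1` for any `c`.
#' @export
cpt_weight <- function(p, c) {
  pc <- p^c
  pc / (pc + (1 - p)^c)^(1 / c)
}

#' Cumulative-prospect-theory decision values
#'
#' Magnitudes pass through a power value function with loss aversion
#' `lambda` (`Mag^alpha` for gains, `-lambda * (-Mag)^beta` for losses);
#' item probabilities pass through an inverse-S weighting function with
#' curvature `gamma` (gain options) or `delta` (loss options) and are then
#' averaged per option.
#'
#' @param par Vector `c(alpha, beta, lambda, gamma, delta, b1..b6)`.
#' @inheritParams mvs_dv
#' @return n x 2 matrix of decision values.
#' @export
cpt_dv <- function(par, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  n <- data$n
  alpha <- par[1]; beta <- par[2]; lambda <- par[3]
  gam <- par[4]; del <- par[5]
  maghat <- ifelse(data$Mag >= 0, data$Mag^alpha, -lambda * (-data$Mag)^beta)
  probhat <- matrix(0, n, 2)
  for (k in 1:2) {
    M <- matrix(data$P[, , k], nrow = n)
    cvec <- ifelse(data$Mag[, k] >= 0, gam, del)
    W <- cpt_weight(M, matrix(cvec, n, ncol(M)))
    probhat[, k] <- rowMeans(W)
  }
  dv_core(par[6:11], maghat, probhat, data$Bon, data$Cond)
}

#' Logistic decision-value GLM
#'
#' A single rightward decision value
#' `DV_R = b0 + b1*Mag_(R-L) + b2*Prob_(R-L) + b3*Bon + b4*Cond +
#' b5*(Mag_R*Prob_R - Mag_L*Prob_L) + b6*(Prob_(R-L)*Bon*Cond)` scored
#' through a logistic link. Returned as the DV pair `(0, DV_R)` so the
#' shared softmax contract applies (`softmax(0, x) = plogis(x)`).
#'
#' @param par Vector `c(b0..b6)`.
#' @inheritParams mvs_dv
#' @return n x 2 matrix of decision values.
#' @export
glm_dv <- function(par, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  X <- glm_dv_features(data)
  cbind(0, as.numeric(cbind(1, X) %*% par))
}

# regressor matrix shared by glm_dv and the closed-form logistic fit
glm_dv_features <- function(data) {
  n <- data$n
  pm <- sapply(1:2, function(k) rowMeans(matrix(data$P[, , k], nrow = n)))
  pm <- matrix(pm, nrow = n)
  ev <- data$Mag * pm
  cbind(mag_rl = data$Mag[, 2] - data$Mag[, 1],
        prob_rl = pm[, 2] - pm[, 1],
        bon = data$Bon, cond = data$Cond,
        ev_rl = ev[, 2] - ev[, 1],
        pbc = (pm[, 2] - pm[, 1]) * data$Bon * data$Cond)
}

#' Autoencoder decision values
#'
#' A single sigmoid hidden layer over the option feature vector
#' `[Mag_L, Mag_R, Prob_L, Prob_R, Bon, Cond, EV_L, EV_R,
#' (Prob*Bon*Cond)_L, (Prob*Bon*Cond)_R]`, read out linearly into one DV
#' per option.
#'
#' @param params List with `W4` (hidden x 10), `b4` (hidden), `W5`
#'   (2 x hidden), `b5` (2).
#' @inheritParams mvs_dv
#' @return n x 2 matrix of decision values.
#' @export
autoencoder_dv <- function(params, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  X <- autoencoder_features(data)
  Z <- stats::plogis(X %*% t(params$W4) + rep(params$b4, each = nrow(X)))
  Z %*% t(params$W5) + rep(params$b5, each = nrow(X))
}

autoencoder_features <- function(data) {
  n <- data$n
  pm <- matrix(sapply(1:2, function(k) rowMeans(matrix(data$P[, , k], nrow = n))), nrow = n)
  ev <- data$Mag * pm
  pbc <- pm * data$Bon * data$Cond
  cbind(data$Mag[, 1], data$Mag[, 2], pm[, 1], pm[, 2], data$Bon, data$Cond,
        ev[, 1], ev[, 2], pbc[, 1], pbc[, 2])
}

# ---------------------------------------------------------------- registry

parametric_registry <- function() {
  list(
    mvs = list(
      type = "parametric", npar = 8L,
      par_names = c("rho", "sigma", paste0("b", 1:6)),
      lower = c(-10, -10, rep(-10, 6)), upper = c(10, 10, rep(10, 6)),
      start = c(0, 0, rep(0.1, 6)), dv = mvs_dv),
    power = list(
      type = "parametric", npar = 7L,
      par_names = c("g", paste0("b", 1:6)),
      lower = c(0.05, rep(-10, 6)), upper = c(10, rep(10, 6)),
      start = c(1, rep(0.1, 6)), dv = power_dv),
    cpt = list(
      type = "parametric", npar = 11L,
      par_names = c("alpha", "beta", "lambda", "gamma", "delta", paste0("b", 1:6)),
      lower = c(0.2, 0.2, 0, 0.2, 0.2, rep(-10, 6)),
      upper = c(2, 2, 5, 1.5, 1.5, rep(10, 6)),
      start = c(1, 1, 1, 1, 1, rep(0.1, 6)), dv = cpt_dv),
    glm = list(
      type = "parametric", npar = 7L,
      par_names = paste0("b", 0:6),
      lower = rep(-20, 7), upper = rep(20, 7),
      start = rep(0, 7), dv = glm_dv),
    ev = list(
      type = "parametric", npar = 0L, par_names = character(0),
      dv = function(par, data) glm_dv(c(0, 0, 0, 0, 0, 1, 0), data))
  )
}

#' List registered decision models
#'
#' @return Character vector of model identifiers accepted by
#'   [fit_model()] and [simulate_agent()].
#' @export
model_ids <- function() {
  c(names(parametric_registry()), "autoenc", "cnn", "ann",
    paste0("cnn_", c("mean", "mean_var", "mean_skew", "var_skew", "mean_var_skew")))
}

#' Decision values under a named model
#'
#' Dispatches to the registered model's DV function. Network models
#' (`cnn`, `ann`, `cnn_*`, `autoenc`) expect `params` in their structured
#' form (see [cnn_init()], [net_init()]); parametric models expect a
#' numeric vector.
#'
#' @param model Model identifier (see [model_ids()]).
#' @param params Model parameters.
#' @param data A `choice_dataset`, `task_design`, or internal `model_data`
#'   list.
#' @param stage Task stage the data refer to (1 or 2).
#' @return n x 2 matrix of decision values.
#' @export
model_dv <- function(model, params, data, stage = 1L) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, stage)
  reg <- parametric_registry()
  if (model %in% names(reg)) return(reg[[model]]$dv(params, data))
  if (model == "autoenc") return(autoencoder_dv(params, data))
  net_forward(params, data)$dv
}

#' Choice probabilities under a named model
#'
#' @inheritParams model_dv
#' @param temperature Softmax temperature; probabilities are
#'   `softmax(DV / temperature)`. As `temperature -> 0` choice becomes
#'   greedy; as `temperature -> Inf` it approaches indifference.
#' @return n x 2 matrix of choice probabilities (left, right).
#' @export
model_prob <- function(model, params, data, stage = 1L, temperature = 1) {
  if (temperature <= 0) stop("temperature must be positive; use predict_greedy for the limit", call. = FALSE)
  softmax2(model_dv(model, params, data, stage) / temperature)
}
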