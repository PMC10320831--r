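# Cross-validated model fitting and likelihood-based comparison. Choices
# are pooled across subjects, split at random into k folds, and each model
# is trained on k-1 folds and scored on the held-out fold, yielding k
# held-out negative log likelihoods per model. Parametric models are fitted
# by bounded maximum likelihood with multiple random restarts; networks by
# gradient descent (see train_net()).

data_subset <- function(data, idx) {
  out <- data
  out$P <- data$P[idx, , , drop = FALSE]
  out$Mag <- data$Mag[idx, , drop = FALSE]
  for (nm in c("Bon", "Cond", "choice", "block", "subject", "onset"))
    out[[nm]] <- data[[nm]][idx]
  out$n <- length(idx)
  out
}

nll_of_prob <- function(p_right, choice) {
  pc <- ifelse(choice == 1, p_right, 1 - p_right)
  -sum(log(pmax(pc, 1e-12)))
}

# likelihood closures with the expensive per-dataset quantities (moments,
# reshaped probability matrices, feature matrices) hoisted out of the
# optimizer loop; numerically identical to the exported *_dv() functions
make_negll <- function(model, data) {
  n <- data$n
  y <- data$choice
  nll_dv <- function(dv) {
    if (any(!is.finite(dv))) return(1e10)
    nll_of_prob(softmax2(dv)[, 2], y)
  }
  if (model == "mvs") {
    mom <- option_moments(data$P)
    function(par) {
      probhat <- mom$mean + par[1] * mom$variance + par[2] * mom$skewness
      nll_dv(dv_core(par[3:8], data$Mag, probhat, data$Bon, data$Cond))
    }
  } else if (model == "power") {
    PL <- matrix(data$P[, , 1], nrow = n); PR <- matrix(data$P[, , 2], nrow = n)
    function(par) {
      probhat <- cbind(rowMeans(PL^par[1]), rowMeans(PR^par[1]))
      nll_dv(dv_core(par[2:7], data$Mag, probhat, data$Bon, data$Cond))
    }
  } else if (model == "cpt") {
    PL <- matrix(data$P[, , 1], nrow = n); PR <- matrix(data$P[, , 2], nrow = n)
    QL <- 1 - PL; QR <- 1 - PR
    gainL <- data$Mag[, 1] >= 0; gainR <- data$Mag[, 2] >= 0
    cw <- function(PC, QC, c) { pc <- PC^c; pc / (pc + QC^c)^(1 / c) }
    function(par) {
      maghat <- ifelse(data$Mag >= 0, data$Mag^par[1], -par[3] * (-data$Mag)^par[2])
      cL <- ifelse(gainL, par[4], par[5]); cR <- ifelse(gainR, par[4], par[5])
      probhat <- cbind(rowMeans(cw(PL, QL, cL)), rowMeans(cw(PR, QR, cR)))
      nll_dv(dv_core(par[6:11], maghat, probhat, data$Bon, data$Cond))
    }
  } else {
    reg <- parametric_registry()[[model]]
    function(par) nll_dv(reg$dv(par, data))
  }
}

# Profiled maximum likelihood for the two-DV parametric models. The bonus
# and condition main effects (b3, b4) are identical for both options and
# cancel in the softmax, and the remaining weights (b1, b2, b5, b6) enter
# the DV difference linearly. So for fixed nonlinear parameters theta the
# inner problem is a no-intercept logistic regression, solved exactly by
# IRLS; the outer optimizer only searches theta. This is the exact MLE of
# the full likelihood (b3 = b4 = 0 reported, being unidentifiable from
# choices).
profiled_spec <- function(model, data) {
  n <- data$n
  y <- data$choice
  mom <- if (model == "mvs") option_moments(data$P)
  PL <- matrix(data$P[, , 1], nrow = n); PR <- matrix(data$P[, , 2], nrow = n)
  LPL <- log(pmax(PL, 1e-12)); LPR <- log(pmax(PR, 1e-12))
  LQL <- log(pmax(1 - PL, 1e-12)); LQR <- log(pmax(1 - PR, 1e-12))
  gainL <- data$Mag[, 1] >= 0; gainR <- data$Mag[, 2] >= 0
  hat <- switch(model,
    mvs = function(theta) {
      list(mag = data$Mag,
           prob = mom$mean + theta[1] * mom$variance + theta[2] * mom$skewness)
    },
    power = function(theta) {
      list(mag = data$Mag,
           prob = cbind(rowMeans(exp(theta[1] * LPL)), rowMeans(exp(theta[1] * LPR))))
    },
    cpt = function(theta) {
      maghat <- ifelse(data$Mag >= 0, data$Mag^theta[1],
                       -theta[3] * (-data$Mag)^theta[2])
      cL <- ifelse(gainL, theta[4], theta[5]); cR <- ifelse(gainR, theta[4], theta[5])
      wL <- exp(cL * LPL) / (exp(cL * LPL) + exp(cL * LQL))^(1 / cL)
      wR <- exp(cR * LPR) / (exp(cR * LPR) + exp(cR * LQR))^(1 / cR)
      list(mag = maghat, prob = cbind(rowMeans(wL), rowMeans(wR)))
    })
  design <- function(theta) {
    h <- hat(theta)
    cbind(h$mag[, 2] - h$mag[, 1],
          h$prob[, 2] - h$prob[, 1],
          h$mag[, 2] * h$prob[, 2] - h$mag[, 1] * h$prob[, 1],
          (h$prob[, 2] - h$prob[, 1]) * data$Bon * data$Cond)
  }
  inner <- function(theta) {
    X <- design(theta)
    if (any(!is.finite(X))) return(list(nll = 1e10, beta = rep(0, 4)))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit)) return(list(nll = 1e10, beta = rep(0, 4)))
    beta <- fit$coefficients
    beta[!is.finite(beta)] <- 0
    list(nll = fit$deviance / 2, beta = beta)
  }
  nth <- switch(model, mvs = 2L, power = 1L, cpt = 5L)
  reg <- parametric_registry()[[model]]
  expand <- function(theta, beta) {
    full <- c(theta, beta[1], beta[2], 0, 0, beta[3], beta[4])
    stats::setNames(full, reg$par_names)
  }
  list(negll = function(theta) inner(theta)$nll, inner = inner,
       expand = expand, nth = nth,
       lower = reg$lower[seq_len(nth)], upper = reg$upper[seq_len(nth)],
       start = reg$start[seq_len(nth)])
}

fit_parametric <- function(model, data, seed, restarts = 10L, maxit = 300L) {
  reg <- parametric_registry()[[model]]
  if (model == "ev") return(list(par = numeric(0), nll = nll_of_prob(
    softmax2(glm_dv(c(0, 0, 0, 0, 0, 1, 0), data))[, 2], data$choice), convergence = 0L))
  if (model == "glm") {
    X <- glm_dv_features(data)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), data$choice,
                                           family = stats::binomial()))
    par <- as.numeric(fit$coefficients)
    par[!is.finite(par)] <- 0
    return(list(par = par, nll = nll_of_prob(
      softmax2(glm_dv(par, data))[, 2], data$choice), convergence = 0L))
  }
  ps <- profiled_spec(model, data)
  starts <- with_seed(derive_seed(seed, paste0("fit_", model)), function() {
    s <- list(ps$start)
    for (r in seq_len(max(restarts - 1L, 0L))) {
      lo <- pmax(ps$lower, -2); hi <- pmin(ps$upper, 2)
      s[[r + 1L]] <- stats::runif(ps$nth, lo, hi)
    }
    s
  })
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, ps$negll, method = "L-BFGS-B",
                   lower = ps$lower, upper = ps$upper,
                   control = list(maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed for model ", model, call. = FALSE)
  if (best$convergence != 0)
    warning("optimizer did not formally converge for model ", model,
            "; best restart retained", call. = FALSE)
  list(par = ps$expand(best$par, ps$inner(best$par)$beta), nll = best$value,
       convergence = best$convergence)
}

#' Fit a decision model with k-fold cross-validation
#'
#' Pools choices across subjects, assigns trials to `folds` random folds
#' (seeded), trains the model on each training set and records the
#' held-out negative log likelihood (both per-fold sum and per-trial
#' mean), held-out choice probabilities, and prediction accuracy (fraction
#' of held-out trials where the probability of the made choice exceeds
#' 0.5; exact ties count as incorrect). A final instance trained on all
#' trials is stored in `$full` for downstream feature and
#' representational analyses.
#'
#' @param model Model identifier (see [model_ids()]).
#' @param dataset A `choice_dataset` with observed choices.
#' @param stage Task stage to fit (1 or 2).
#' @param folds Number of folds (default 20).
#' @param seed Integer seed governing fold assignment, restarts, and
#'   network initialization.
#' @param control List of fitting options: `restarts` (parametric
#'   multi-start count, default 10), `maxit`, `epochs`, `lr`, `config` (a
#'   [net_config()] for network models), `refit_full` (default `TRUE`).
#' @return A `model_fit` object.
#' @export
fit_model <- function(model, dataset, stage = 1L, folds = 20L, seed = 1L,
                      control = list()) {
  stopifnot(model %in% model_ids(), folds >= 2L)
  data <- model_data(dataset, stage)
  if (data$n == 0L) stop("dataset has no trials at stage ", stage, call. = FALSE)
  is_param <- model %in% names(parametric_registry())
  config <- control$config
  if (!is_param && is.null(config)) config <- net_config(model)
  fold_of <- with_seed(derive_seed(seed, "folds"),
                       function() sample(rep_len(seq_len(folds), data$n)))
  trial_prob <- rep(NA_real_, data$n)
  fold_par <- vector("list", folds)
  nll_sum <- nll_mean <- acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold_of != k); te <- which(fold_of == k)
    dtr <- data_subset(data, tr); dte <- data_subset(data, te)
    if (is_param) {
      fk <- fit_parametric(model, dtr, seed = derive_seed(seed, paste0("fold", k)),
                           restarts = control$restarts %||% 10L,
                           maxit = control$maxit %||% 300L)
      par <- fk$par
      p_te <- softmax2(model_dv(model, par, dte, stage))[, 2]
    } else {
      par <- train_net(dtr, config, stage = stage,
                       seed = derive_seed(seed, paste0("fold", k)),
                       epochs = control$epochs %||% 400L,
                       lr = control$lr %||% 0.02,
                       decay = control$decay %||% 0)
      p_te <- net_forward(par, dte)$p[, 2]
    }
    fold_par[[k]] <- par
    trial_prob[te] <- p_te
    pc <- ifelse(dte$choice == 1, p_te, 1 - p_te)
    nll_sum[k] <- -sum(log(pmax(pc, 1e-12)))
    nll_mean[k] <- nll_sum[k] / length(te)
    acc[k] <- mean(pc > 0.5)
  }
  full <- NULL
  if (control$refit_full %||% TRUE) {
    full <- if (is_param) {
      fit_parametric(model, data, seed = derive_seed(seed, "full"),
                     restarts = control$restarts %||% 10L,
                     maxit = control$maxit %||% 300L)$par
    } else {
      train_net(data, config, stage = stage, seed = derive_seed(seed, "full"),
                epochs = control$epochs %||% 400L, lr = control$lr %||% 0.02,
                decay = control$decay %||% 0)
    }
  }
  structure(list(model = model, stage = as.integer(stage), folds = folds,
                 seed = as.integer(seed), fold_of = fold_of,
                 fold_params = fold_par, fold_nll_sum = nll_sum,
                 fold_nll_mean = nll_mean, fold_accuracy = acc,
                 trial_prob = trial_prob, accuracy = mean(acc),
                 config = config, full = full, n_trials = data$n),
            class = "model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit '%s': %d folds, mean held-out NLL/trial %.4f, accuracy %.3f\n",
              x$model, x$folds, mean(x$fold_nll_mean), x$accuracy))
  invisible(x)
}

#' Compare fitted models by held-out likelihood
#'
#' Summarizes each fit's held-out NLL (per-trial mean over folds, with
#' SEM over folds) and prediction accuracy, and runs pairwise
#' independent-samples t-tests on the per-fold NLL values (pooled-variance
#' Student t; df = 2 * folds - 2, i.e. 38 for two 20-fold fits).
#'
#' @param fits List of `model_fit` objects (named or not).
#' @param statistic Which per-fold NLL to compare: `"mean"` (per-trial
#'   mean, default) or `"sum"` (fold total).
#' @return List with `table` (one row per model: mean NLL, SEM,
#'   accuracy), and `t`, `p`, `df` matrices of pairwise tests.
#' @export
compare_models <- function(fits, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (inherits(fits, "model_fit")) fits <- list(fits)
  ids <- vapply(fits, function(f) f$model, character(1))
  val <- lapply(fits, function(f)
    if (statistic == "mean") f$fold_nll_mean else f$fold_nll_sum)
  tab <- data.frame(model = ids,
                    nll = vapply(val, mean, numeric(1)),
                    sem = vapply(val, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
                    accuracy = vapply(fits, function(f) f$accuracy, numeric(1)))
  m <- length(fits)
  tmat <- pmat <- dfmat <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (stats::sd(c(val[[i]], val[[j]])) < 1e-14) {
      tmat[i, j] <- 0; pmat[i, j] <- 1
      dfmat[i, j] <- length(val[[i]]) + length(val[[j]]) - 2
    } else {
      tt <- stats::t.test(val[[i]], val[[j]], var.equal = TRUE)
      tmat[i, j] <- unname(tt$statistic)
      pmat[i, j] <- tt$p.value
      dfmat[i, j] <- unname(tt$parameter)
    }
  }
  list(table = tab, t = tmat, p = pmat, df = dfmat, statistic = statistic)
}

#' Serialize a model fit to JSON
#'
#' Writes the fit's metadata, per-fold held-out statistics, and parameters
#' (including network weight matrices and stored standardization
#' constants) to a single JSON file readable by [read_model_fit()].
#'
#' @param fit A `model_fit`.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_model_fit <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  ser_par <- function(p) {
    if (inherits(p, "net_params")) {
      list(net = TRUE, q = p$q, config = unclass(p$config), std = p$std,
           W1 = if (!is.null(p$W1)) as.list(as.data.frame(p$W1)),
           b1 = p$b1, W2 = as.list(as.data.frame(p$W2)), b2 = p$b2,
           W3 = as.list(as.data.frame(p$W3)), b3 = p$b3)
    } else list(net = FALSE, par = as.list(p))
  }
  out <- list(model = fit$model, stage = fit$stage, folds = fit$folds,
              seed = fit$seed, fold_of = fit$fold_of,
              fold_nll_sum = fit$fold_nll_sum, fold_nll_mean = fit$fold_nll_mean,
              fold_accuracy = fit$fold_accuracy, accuracy = fit$accuracy,
              trial_prob = fit$trial_prob, n_trials = fit$n_trials,
              fold_params = lapply(fit$fold_params, ser_par),
              full = if (!is.null(fit$full)) ser_par(fit$full))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model fit written by [write_model_fit()]
#'
#' @param path Path to the JSON file.
#' @return A `model_fit` object.
#' @export
read_model_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  deser_par <- function(p) {
    if (is.null(p)) return(NULL)
    if (!isTRUE(p$net)) return(unlist(p$par))
    cfg <- structure(p$config, class = "net_config")
    mat <- function(x) unname(do.call(cbind, lapply(x, as.numeric)))
    out <- list(config = cfg, q = as.integer(p$q), std = p$std,
                W2 = mat(p$W2), b2 = as.numeric(p$b2),
                W3 = mat(p$W3), b3 = as.numeric(p$b3))
    if (!is.null(p$W1)) { out$W1 <- mat(p$W1); out$b1 <- as.numeric(p$b1) }
    structure(out, class = "net_params")
  }
  structure(list(model = raw$model, stage = as.integer(raw$stage),
                 folds = as.integer(raw$folds), seed = as.integer(raw$seed),
                 fold_of = as.integer(raw$fold_of),
                 fold_params = lapply(raw$fold_params, deser_par),
                 fold_nll_sum = raw$fold_nll_sum,
                 fold_nll_mean = raw$fold_nll_mean,
                 fold_accuracy = raw$fold_accuracy,
                 trial_prob = raw$trial_prob, accuracy = raw$accuracy,
                 config = if (!is.null(raw$full$config))
                   structure(raw$full$config, class = "net_config"),
                 full = deser_par(raw$full), n_trials = raw$n_trials),
            class = "model_fit")
}
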