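# Feature-map decomposition of the convolutional network's decision value.
# The "partial DV" of detector d is the network's forward pass with every
# other detector's post-convolution feature maps (both the probability maps
# and their magnitude-scaled copies) set to zero, keeping the trained
# weights, biases, and the magnitude/bonus/condition channels intact. The
# partial DVs are then correlated with the between-environment differences
# in the statistical moments of the item probabilities.

#' Partial decision values of one feature detector
#'
#' @param params Trained `net_params` of a `"cnn"` model (e.g.
#'   `fit$full`).
#' @param data A `choice_dataset`, `task_design`, or model-data list.
#' @param detector Detector index to keep (1-based).
#' @return n x 2 matrix of partial decision values.
#' @export
partial_dv <- function(params, data, detector) {
  stopifnot(inherits(params, "net_params"), params$config$model == "cnn")
  net_forward(params, data, stage = 1L, keep_detector = detector)$dv
}

#' Per-trial, per-detector partial DV table
#'
#' One row per stage-1 trial with the rightward-minus-leftward partial DV
#' of each detector plus the between-environment differences in mean,
#' variance, and skewness of the item probabilities.
#'
#' @param params Trained `net_params` of a `"cnn"` model.
#' @param data A `choice_dataset` or `task_design`.
#' @return Data frame with columns `pdv_1..pdv_F`, `d_mean`,
#'   `d_variance`, `d_skewness`.
#' @export
partial_dv_table <- function(params, data) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, 1L)
  Fn <- params$config$n_detectors
  out <- as.data.frame(sapply(seq_len(Fn), function(f) {
    dv <- partial_dv(params, data, f)
    dv[, 2] - dv[, 1]
  }))
  names(out) <- paste0("pdv_", seq_len(Fn))
  mom <- option_moments(data$P)
  out$d_mean <- mom$mean[, 2] - mom$mean[, 1]
  out$d_variance <- mom$variance[, 2] - mom$variance[, 1]
  out$d_skewness <- mom$skewness[, 2] - mom$skewness[, 1]
  out
}

#' Correlate partial DVs with environment moment differences
#'
#' Pearson correlation (two-tailed) of each detector's partial DV
#' difference with the between-environment differences in mean, variance,
#' and skewness.
#'
#' @param table Output of [partial_dv_table()].
#' @return Data frame with one row per detector x moment: `detector`,
#'   `moment`, `r`, `p`, `n`.
#' @export
moment_correlations <- function(table) {
  pdv <- grep("^pdv_", names(table), value = TRUE)
  moms <- c("d_mean", "d_variance", "d_skewness")
  out <- expand.grid(detector = seq_along(pdv), moment = moms,
                     stringsAsFactors = FALSE)
  out$r <- out$p <- NA_real_
  out$n <- nrow(table)
  for (i in seq_len(nrow(out))) {
    ct <- stats::cor.test(table[[pdv[out$detector[i]]]], table[[out$moment[i]]])
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out[, c("detector", "moment", "r", "p", "n")]
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's (1980) z for the difference between `r1 = cor(x, y1)` and
#' `r2 = cor(x, y2)` given `r12 = cor(y1, y2)`, all measured on the same
#' `n` cases. Used to ask whether one detector's partial DV tracks a
#' moment more strongly than another detector's does.
#'
#' @param r1,r2 The two correlations with the shared variable.
#' @param r12 Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @return List with `z` and two-tailed `p`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  if (any(abs(c(r1, r2, r12)) >= 1))
    stop("degenerate correlation (|r| >= 1)", call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r12) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
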