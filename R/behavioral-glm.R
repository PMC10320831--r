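# Behavioral logistic regressions. Choices (right = 1) are regressed per
# subject on option-difference regressors, then each coefficient is tested
# against zero across subjects with a one-sample t (df = n_subjects - 1).

glm1_regressors <- function(data) {
  n <- data$n
  pm <- matrix(sapply(1:2, function(k) rowMeans(matrix(data$P[, , k], nrow = n))), nrow = n)
  ev <- data$Mag * pm
  data.frame(ev_rl = ev[, 2] - ev[, 1],
             prob_rl = pm[, 2] - pm[, 1],
             bon = data$Bon, cond = data$Cond,
             ev_bon_cond = (ev[, 2] - ev[, 1]) * data$Bon * data$Cond,
             prob_bon_cond = (pm[, 2] - pm[, 1]) * data$Bon * data$Cond)
}

glm2_regressors <- function(data) {
  n <- data$n
  pm <- matrix(sapply(1:2, function(k) rowMeans(matrix(data$P[, , k], nrow = n))), nrow = n)
  ev <- data$Mag * pm
  mom <- option_moments(data$P)
  data.frame(ev_rl = ev[, 2] - ev[, 1],
             mean_rl = mom$mean[, 2] - mom$mean[, 1],
             variance_rl = mom$variance[, 2] - mom$variance[, 1],
             skewness_rl = mom$skewness[, 2] - mom$skewness[, 1])
}

fit_choice_glm <- function(dataset, stage, regressor_fun, standardize = TRUE) {
  data <- model_data(dataset, stage)
  subjects <- sort(unique(data$subject))
  if (length(subjects) < 2L)
    stop("group-level tests require at least 2 subjects", call. = FALSE)
  X0 <- regressor_fun(data)
  coefs <- matrix(NA_real_, length(subjects), ncol(X0) + 1L,
                  dimnames = list(subjects, c("intercept", names(X0))))
  flagged <- character(0)
  for (i in seq_along(subjects)) {
    idx <- which(data$subject == subjects[i])
    y <- data$choice[idx]
    if (length(unique(y)) < 2L) {
      flagged <- c(flagged, as.character(subjects[i]))
      next
    }
    X <- X0[idx, , drop = FALSE]
    if (standardize) X <- as.data.frame(lapply(X, zscore))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || any(abs(stats::coef(fit)) > 50, na.rm = TRUE)) {
      flagged <- c(flagged, as.character(subjects[i]))
      next
    }
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- NA_real_
    coefs[i, ] <- cf
  }
  if (length(flagged) > 0)
    warning("subject(s) excluded (perfect separation or degenerate fit): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  ok <- stats::complete.cases(coefs)
  if (sum(ok) < 2L)
    stop("fewer than 2 subjects with identifiable fits (no-information or separated data)",
         call. = FALSE)
  grp <- t(apply(coefs[ok, , drop = FALSE], 2, function(b) {
    if (length(b) < 2L || stats::sd(b) < 1e-14)
      return(c(mean = mean(b), t = if (all(b == 0)) 0 else Inf, df = length(b) - 1, p = NA))
    tt <- stats::t.test(b)
    c(mean = mean(b), t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }))
  structure(list(coefficients = coefs, group = as.data.frame(grp),
                 flagged = flagged, n_subjects = sum(ok),
                 standardized = standardize),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("choice GLM over %d subjects%s\n", x$n_subjects,
              if (length(x$flagged)) paste0(" (", length(x$flagged), " excluded)") else ""))
  print(round(x$group, 4))
  invisible(x)
}

#' Behavioral GLM1: value, probability, and bonus-adaptation effects
#'
#' Per-subject logistic regression of rightward choice on `EV_(R-L)`,
#' `Prob_(R-L)`, bonus, condition (linked = 1), and the three-way
#' interactions `EV_(R-L) x Bon x Cond` and `Prob_(R-L) x Bon x Cond`,
#' followed by group one-sample t-tests on each coefficient. `Prob` is
#' the mean item probability of an environment (stage 1) or the item
#' probability (stage 2); environment EV is the displayed mean magnitude
#' times the mean probability.
#'
#' @param dataset A `choice_dataset` with >= 2 subjects.
#' @param stage Task stage to analyze (1 or 2).
#' @param standardize Z-score regressors within subject before fitting
#'   (default `TRUE`); interactions are formed before standardization.
#' @return A `glm_result`: per-subject coefficient matrix, group table
#'   (`mean`, `t`, `df`, `p`), and flagged subjects (perfect separation
#'   or degenerate fits are excluded with a warning, never silent
#'   infinities).
#' @export
fit_glm1 <- function(dataset, stage = 1L, standardize = TRUE) {
  fit_choice_glm(dataset, stage, glm1_regressors, standardize)
}

#' Behavioral GLM2: statistical-moment preferences
#'
#' Per-subject logistic regression of rightward environment choice on
#' `EV_(R-L)` and the between-environment differences in mean, variance,
#' and standardized skewness of the item reward probabilities, followed
#' by group one-sample t-tests.
#'
#' @inheritParams fit_glm1
#' @return A `glm_result`.
#' @export
fit_glm2 <- function(dataset, standardize = TRUE) {
  fit_choice_glm(dataset, 1L, glm2_regressors, standardize)
}
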