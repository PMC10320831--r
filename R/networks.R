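# Network decision models: the convolutional network for environment
# choice, its moment-input "simplified" variants, the dense network for
# item choice, and the sigmoid autoencoder. All are trained by full-batch
# gradient descent with adaptive moments (Adam) on softmax cross-entropy,
# with manual backpropagation: the networks are small enough that no
# deep-learning framework is needed.

#' Network configuration
#'
#' @param model Network identifier: `"cnn"`, `"ann"`, `"autoenc"`, or a
#'   simplified moment-input variant `"cnn_mean"`, `"cnn_mean_var"`,
#'   `"cnn_mean_skew"`, `"cnn_var_skew"`, `"cnn_mean_var_skew"`.
#' @param n_detectors Number of feature detectors (`cnn` only; default 4).
#' @param detector_shape Detector size `c(M, N)`; detectors slide along the
#'   item axis of the probability input, so `N` must be 1 inside the
#'   network (the standalone [convolve_map()] is fully general).
#' @param n_hidden Hidden-layer width (default 512).
#' @param standardize Z-score each input channel over the training set and
#'   reuse the stored constants at test time (default `TRUE`).
#' @param symmetric Make decision values label-equivariant by construction:
#'   the forward pass is averaged with the pass on the option-swapped
#'   input, so identical options receive identical DVs exactly and
#'   relabeling left/right mirrors the output (default `TRUE`).
#' @return A list of class `net_config`.
#' @export
net_config <- function(model = "cnn", n_detectors = 4L, detector_shape = c(2L, 1L),
                       n_hidden = 512L, standardize = TRUE, symmetric = TRUE) {
  stopifnot(model %in% c("cnn", "ann", "autoenc",
                         paste0("cnn_", c("mean", "mean_var", "mean_skew",
                                          "var_skew", "mean_var_skew"))))
  if (model == "cnn" && detector_shape[2] != 1L)
    stop("in-network detectors must have N = 1 (one column per option)", call. = FALSE)
  structure(list(model = model, n_detectors = as.integer(n_detectors),
                 detector_shape = as.integer(detector_shape),
                 n_hidden = as.integer(n_hidden), standardize = standardize,
                 symmetric = symmetric,
                 act = if (model == "autoenc") "sigmoid" else "relu"),
            class = "net_config")
}

moment_channels <- function(model) {
  switch(model,
    cnn_mean = "mean", cnn_mean_var = c("mean", "variance"),
    cnn_mean_skew = c("mean", "skewness"), cnn_var_skew = c("variance", "skewness"),
    cnn_mean_var_skew = c("mean", "variance", "skewness"), NULL)
}

#' Valid cross-correlation of a kernel over a matrix
#'
#' Slides an `M x N` detector over an `I x J` input with stride 1 and no
#' padding (no kernel flip): entry `(i, j)` of the output is
#' `b + sum_{m,n} W[m, n] * X[i + m - 1, j + n - 1]`, giving an
#' `(I - M + 1) x (J - N + 1)` feature map.
#'
#' @param X Input matrix.
#' @param W Detector weight matrix.
#' @param b Scalar bias.
#' @return The feature map matrix.
#' @export
convolve_map <- function(X, W, b = 0) {
  X <- as.matrix(X); W <- as.matrix(W)
  I <- nrow(X); J <- ncol(X); M <- nrow(W); N <- ncol(W)
  if (M > I || N > J) stop("detector larger than input", call. = FALSE)
  out <- matrix(b, I - M + 1L, J - N + 1L)
  for (m in seq_len(M)) for (n in seq_len(N)) {
    out <- out + W[m, n] * X[m:(I - M + m), n:(J - N + n), drop = FALSE]
  }
  out
}

#' Assemble the network input for one block
#'
#' Returns the raw (or channel-standardized) probability matrix `X`
#' (items x 2 options, columns ordered left then right), the option
#' magnitudes, and the bonus scalar and condition flag fed to the network.
#'
#' @param block A block from a [generate_task()] design, or a list with
#'   `env_left`, `env_right`, `bonus`, `bonus_condition`.
#' @param std Optional standardizer (from a fitted network); `NULL` leaves
#'   inputs raw.
#' @return List with `X`, `magnitudes`, `bonus`, `condition`.
#' @export
build_cnn_input <- function(block, std = NULL) {
  if (length(block$env_left$item_probs) != length(block$env_right$item_probs))
    stop("options must have equal item counts", call. = FALSE)
  X <- cbind(left = block$env_left$item_probs, right = block$env_right$item_probs)
  mags <- c(block$env_left$mean_mag, block$env_right$mean_mag)
  bon <- block$bonus
  cond <- as.numeric(identical(block$bonus_condition, "linked"))
  if (!is.null(std)) {
    X <- (X - std$p_m) / std$p_s
    mags <- (mags - std$mag_m) / std$mag_s
    bon <- (bon - std$bon_m) / std$bon_s
  }
  list(X = X, magnitudes = mags, bonus = bon, condition = cond)
}

# channel statistics over a training set; identity when standardize = FALSE
std_fit <- function(data, config) {
  sd0 <- function(x) { s <- stats::sd(x); if (!is.finite(s) || s < 1e-12) 1 else s }
  if (!config$standardize) {
    std <- list(p_m = 0, p_s = 1, mag_m = 0, mag_s = 1, bon_m = 0, bon_s = 1,
                mom_m = c(mean = 0, variance = 0, skewness = 0),
                mom_s = c(mean = 1, variance = 1, skewness = 1),
                feat_m = NULL, feat_s = NULL)
    return(std)
  }
  mom <- option_moments(data$P)
  feats <- autoencoder_features(data)
  list(p_m = mean(data$P), p_s = sd0(as.numeric(data$P)),
       mag_m = mean(data$Mag), mag_s = sd0(as.numeric(data$Mag)),
       bon_m = mean(data$Bon), bon_s = sd0(data$Bon),
       mom_m = vapply(mom, function(m) mean(m), numeric(1)),
       mom_s = vapply(mom, function(m) sd0(as.numeric(m)), numeric(1)),
       feat_m = colMeans(feats), feat_s = apply(feats, 2, sd0))
}

std_apply <- function(data, std) {
  list(Pz = (data$P - std$p_m) / std$p_s,
       Mz = (data$Mag - std$mag_m) / std$mag_s,
       bonz = (data$Bon - std$bon_m) / std$bon_s,
       cond = data$Cond)
}

# concat features for the dense (non-convolutional) networks
dense_features <- function(params, data) {
  config <- params$config
  s <- std_apply(data, params$std)
  n <- data$n
  if (config$model == "ann") {
    Pz <- matrix(s$Pz[, 1, ], nrow = n) # item probabilities, one per option
    return(cbind(Pz, s$Mz, Pz * s$Mz, s$bonz, s$cond))
  }
  if (config$model == "autoenc") {
    F0 <- autoencoder_features(data)
    return(sweep(sweep(F0, 2, params$std$feat_m), 2, params$std$feat_s, "/"))
  }
  ch <- moment_channels(config$model)
  mom <- option_moments(data$P)
  momz <- lapply(ch, function(cc) (mom[[cc]] - params$std$mom_m[[cc]]) / params$std$mom_s[[cc]])
  momz <- do.call(cbind, momz)             # n x (2 * n_channels), L/R per channel
  cbind(momz, s$Mz, momz * cbind(s$Mz, s$Mz)[, rep(1:2, length(ch))], s$bonz, s$cond)
}

concat_width <- function(config, q) {
  F <- config$n_detectors; M <- config$detector_shape[1]
  switch(config$model,
    cnn = { L <- (q - M + 1L) * 2L; 2L * F * L + 4L },
    ann = 8L,
    autoenc = 10L,
    { v <- length(moment_channels(config$model)); 4L * v + 4L })
}

#' Initialize network parameters
#'
#' He-style random initialization scaled to the concat width; the
#' standardizer is fitted later, during [train_net()] or attached from a
#' training fold.
#'
#' @param config A [net_config()].
#' @param q Items per option in the input (20 for environments, 1 for
#'   items).
#' @param seed Integer seed.
#' @return A list of class `net_params`.
#' @export
net_init <- function(config, q = 20L, seed = 1L) {
  with_seed(derive_seed(seed, paste0("init_", config$model)), function() {
    d <- concat_width(config, q)
    H <- config$n_hidden
    params <- list(config = config, q = as.integer(q),
                   std = std_fit(list(P = array(0.5, c(2, q, 2)),
                                      Mag = matrix(0, 2, 2), Bon = c(0, 0),
                                      Cond = c(0, 0), n = 2L),
                                 net_config(config$model, standardize = FALSE)),
                   W2 = matrix(stats::rnorm(d * H, 0, sqrt(2 / d)), d, H),
                   b2 = rep(0, H),
                   W3 = matrix(stats::rnorm(H * 2, 0, sqrt(1 / H)), H, 2),
                   b3 = c(0, 0))
    if (config$model == "cnn") {
      M <- config$detector_shape[1]; F <- config$n_detectors
      params$W1 <- matrix(stats::rnorm(M * F, 0, 0.5), M, F)
      params$b1 <- rep(0, F)
    }
    structure(params, class = "net_params")
  })
}

# feature maps for a batch: list over detectors of n x (q-M+1) x 2 arrays
cnn_fmaps <- function(params, Pz) {
  M <- params$config$detector_shape[1]
  q <- dim(Pz)[2]; n <- dim(Pz)[1]
  lapply(seq_len(params$config$n_detectors), function(f) {
    fm <- array(params$b1[f], c(n, q - M + 1L, 2L))
    for (m in seq_len(M)) {
      fm <- fm + params$W1[m, f] * Pz[, m:(q - M + m), , drop = FALSE]
    }
    fm
  })
}

#' Network forward pass
#'
#' Computes decision values, choice probabilities, and every layer's
#' activations (for representational analyses). The concat vector is, in
#' fixed order: the probability feature maps of each detector (flattened
#' item-then-option), the two option magnitudes, the feature maps scaled
#' by their option's magnitude, the bonus, and the condition flag. For
#' dense variants the feature-map block is replaced by the variant's input
#' features.
#'
#' With `symmetric = TRUE` (the config default) the returned DVs are the
#' average of this pass and the pass on the option-swapped input (with its
#' DVs swapped back), making the model exactly label-equivariant:
#' identical options always receive identical DVs. Layer activations are
#' reported from the unswapped pass; `final` is the symmetrized DV.
#'
#' @param params A `net_params` object (from [net_init()] or
#'   [train_net()]).
#' @param data A `choice_dataset`, `task_design`, or internal model-data
#'   list.
#' @param stage Task stage of the data.
#' @param keep_detector If not `NULL`, zero the post-convolution feature
#'   maps of every detector except this index (partial decision values);
#'   0 zeroes every detector (bias-only baseline).
#' @param act Override the activation (`"relu"`, `"sigmoid"`, or
#'   `"linear"`); default is the config's activation.
#' @return List with `dv` (n x 2), `p` (n x 2), `concat`, and `act`
#'   (layer activations: `input`, `featuremaps`, `hidden`, `final`).
#' @export
net_forward <- function(params, data, stage = NULL,
                        keep_detector = NULL, act = NULL) {
  if (inherits(data, c("choice_dataset", "task_design"))) {
    if (is.null(stage)) stage <- if (params$config$model == "ann") 2L else 1L
    data <- model_data(data, stage)
  }
  n <- data$n
  pa <- net_pass(params, data, keep_detector = keep_detector, act = act)
  dv <- pa$dv
  if (isTRUE(params$config$symmetric)) {
    pb <- net_pass(params, swap_options(data), keep_detector = keep_detector,
                   act = act)
    dv <- (pa$dv + pb$dv[, 2:1, drop = FALSE]) / 2
  }
  if (any(!is.finite(dv)))
    stop("non-finite values in final fully connected layer", call. = FALSE)
  input_act <- cbind(matrix(pa$s$Pz, nrow = n), pa$s$Mz, pa$s$bonz, pa$s$cond)
  list(dv = dv, p = softmax2(dv), concat = pa$C,
       act = list(input = input_act, featuremaps = pa$fm_act,
                  hidden = pa$Y, final = dv))
}

# relabel left/right: options swap, everything shared stays put
swap_options <- function(data) {
  data$P <- data$P[, , 2:1, drop = FALSE]
  data$Mag <- data$Mag[, 2:1, drop = FALSE]
  data
}

# one direction of the forward computation, with the caches backprop needs
net_pass <- function(params, data, keep_detector = NULL, act = NULL) {
  config <- params$config
  n <- data$n
  s <- std_apply(data, params$std)
  if (config$model == "cnn") {
    fmaps <- cnn_fmaps(params, s$Pz)
    if (!is.null(keep_detector)) {
      # 0 = zero every detector's maps (bias-only baseline)
      if (keep_detector < 0 || keep_detector > config$n_detectors)
        stop("detector index out of range", call. = FALSE)
      for (f in seq_along(fmaps)) if (f != keep_detector) fmaps[[f]][] <- 0
    }
    flat <- lapply(fmaps, function(fm) matrix(fm, nrow = n))
    magf <- lapply(fmaps, function(fm) {
      mm <- fm
      mm[, , 1] <- mm[, , 1] * s$Mz[, 1]; mm[, , 2] <- mm[, , 2] * s$Mz[, 2]
      matrix(mm, nrow = n)
    })
    C <- cbind(do.call(cbind, flat), s$Mz, do.call(cbind, magf), s$bonz, s$cond)
    fm_act <- do.call(cbind, flat)
  } else {
    C <- dense_features(params, data)
    fm_act <- C
  }
  if (is.null(act)) act <- config$act
  pre <- C %*% params$W2 + rep(params$b2, each = n)
  Y <- switch(act,
    relu = pmax(pre, 0),
    sigmoid = stats::plogis(pre),
    linear = pre)
  dv <- Y %*% params$W3 + rep(params$b3, each = n)
  list(C = C, pre = pre, Y = Y, dv = dv, s = s, fm_act = fm_act, act = act)
}

#' Train a network on choices by gradient descent
#'
#' Full-batch Adam on softmax cross-entropy with manual backpropagation.
#' Inputs are channel-standardized over the training data (stored in the
#' returned parameters for test-time reuse). With a symmetric config the
#' loss is evaluated on the label-equivariant (two-pass averaged) DVs and
#' gradients flow through both passes. Training stops early when the
#' training NLL plateaus.
#'
#' @param data Internal model-data list, `choice_dataset`, or
#'   `task_design` with observed choices.
#' @param config A [net_config()].
#' @param stage Task stage of the training data.
#' @param seed Integer seed (initialization).
#' @param epochs Maximum epochs (default 400).
#' @param lr Adam step size (default 0.02).
#' @param decay Decoupled L2 weight decay applied to weight matrices (not
#'   biases) each step; guards the over-parameterized concat layer against
#'   overfitting small training sets (default 0).
#' @param tol Relative NLL improvement below which training stops
#'   (checked over 25-epoch windows).
#' @return A `net_params` object with attribute `nll_history`.
#' @export
train_net <- function(data, config, stage = 1L, seed = 1L,
                      epochs = 400L, lr = 0.02, decay = 0, tol = 1e-5) {
  if (inherits(data, c("choice_dataset", "task_design"))) data <- model_data(data, stage)
  if (any(is.na(data$choice))) stop("training data must contain choices", call. = FALSE)
  n <- data$n
  y <- cbind(1 - data$choice, data$choice) # one-hot: col 1 left, col 2 right
  params <- net_init(config, q = data$q, seed = seed)
  params$std <- std_fit(data, config)
  is_cnn <- config$model == "cnn"
  sym <- isTRUE(config$symmetric)
  M <- config$detector_shape[1]
  Fn <- config$n_detectors
  q <- data$q

  dirs <- list(data)
  if (sym) dirs <- c(dirs, list(swap_options(data)))
  svals <- lapply(dirs, std_apply, std = params$std)
  Xfix <- if (!is_cnn) lapply(dirs, function(d) dense_features(params, d))
  # flat precomputations for the convolutional path: Pm[[m]] is the n x 2L
  # matrix of probability inputs offset by m - 1 items; Mzc the matching
  # per-column magnitudes
  flatpre <- NULL
  if (is_cnn) {
    Lw <- q - M + 1L
    flatpre <- lapply(svals, function(s) {
      Pm <- lapply(seq_len(M), function(m)
        matrix(s$Pz[, m:(q - M + m), , drop = FALSE], nrow = n))
      Mzc <- cbind(matrix(s$Mz[, 1], n, Lw), matrix(s$Mz[, 2], n, Lw))
      list(Pm = Pm, Mzc = Mzc, s = s)
    })
  }

  pn <- c("W2", "b2", "W3", "b3", if (is_cnn) c("W1", "b1"))
  mstate <- lapply(pn, function(x) params[[x]] * 0); names(mstate) <- pn
  vstate <- mstate
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8
  hist <- numeric(0)
  best <- Inf

  build_C <- function(di) {
    if (!is_cnn) return(Xfix[[di]])
    fp <- flatpre[[di]]
    flat <- vector("list", Fn); magf <- vector("list", Fn)
    for (f in seq_len(Fn)) {
      fm <- params$b1[f]
      for (m in seq_len(M)) fm <- fm + params$W1[m, f] * fp$Pm[[m]]
      flat[[f]] <- fm
      magf[[f]] <- fm * fp$Mzc
    }
    cbind(do.call(cbind, flat), fp$s$Mz, do.call(cbind, magf),
          fp$s$bonz, fp$s$cond)
  }

  for (ep in seq_len(epochs)) {
    caches <- vector("list", length(dirs))
    for (di in seq_along(dirs)) {
      C <- build_C(di)
      pre <- C %*% params$W2 + rep(params$b2, each = n)
      Y <- if (config$act == "relu") pmax(pre, 0) else stats::plogis(pre)
      dv <- Y %*% params$W3 + rep(params$b3, each = n)
      caches[[di]] <- list(C = C, pre = pre, Y = Y, dv = dv)
    }
    dv <- if (sym) (caches[[1]]$dv + caches[[2]]$dv[, 2:1]) / 2 else caches[[1]]$dv
    p <- softmax2(dv)
    nll <- -mean(log(pmax(rowSums(p * y), 1e-12)))
    hist <- c(hist, nll)

    ddv_all <- (p - y) / n
    g <- lapply(pn, function(x) params[[x]] * 0); names(g) <- pn
    for (di in seq_along(dirs)) {
      ddv <- if (!sym) ddv_all
        else if (di == 1) ddv_all / 2 else ddv_all[, 2:1] / 2
      ca <- caches[[di]]
      g$W3 <- g$W3 + t(ca$Y) %*% ddv
      g$b3 <- g$b3 + colSums(ddv)
      dY <- ddv %*% t(params$W3)
      dpre <- if (config$act == "relu") dY * (ca$pre > 0) else dY * ca$Y * (1 - ca$Y)
      g$W2 <- g$W2 + t(ca$C) %*% dpre
      g$b2 <- g$b2 + colSums(dpre)
      if (is_cnn) {
        fp <- flatpre[[di]]
        dC <- dpre %*% t(params$W2)
        Lw <- q - M + 1L
        seg <- Fn * Lw * 2L
        for (f in seq_len(Fn)) {
          i1 <- (f - 1L) * Lw * 2L
          dfm <- dC[, (i1 + 1L):(i1 + Lw * 2L), drop = FALSE] +
            dC[, (seg + 2L + i1 + 1L):(seg + 2L + i1 + Lw * 2L), drop = FALSE] * fp$Mzc
          for (m in seq_len(M))
            g$W1[m, f] <- g$W1[m, f] + sum(dfm * fp$Pm[[m]])
          g$b1[f] <- g$b1[f] + sum(dfm)
        }
      }
    }
    for (nm in pn) {
      mstate[[nm]] <- b1a * mstate[[nm]] + (1 - b1a) * g[[nm]]
      vstate[[nm]] <- b2a * vstate[[nm]] + (1 - b2a) * g[[nm]]^2
      mh <- mstate[[nm]] / (1 - b1a^ep)
      vh <- vstate[[nm]] / (1 - b2a^ep)
      step <- mh / (sqrt(vh) + epsa)
      if (decay > 0 && nm %in% c("W1", "W2", "W3"))
        step <- step + decay * params[[nm]]
      params[[nm]] <- params[[nm]] - lr * step
    }
    if (ep %% 25L == 0L) {
      if (best - nll < tol * abs(best)) break
      best <- min(best, nll)
    }
  }
  attr(params, "nll_history") <- hist
  params
}
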