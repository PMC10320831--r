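# Representational similarity analysis. A representational dissimilarity
# matrix (RDM) is 1 minus the pairwise Pearson correlation of trial
# activation patterns; two RDMs are compared by the Spearman correlation of
# their strictly-upper-triangle entries. Group inference uses a Wilcoxon
# signed-rank test of per-subject correlations against zero and a
# trial-label permutation test.

#' Compute a representational dissimilarity matrix
#'
#' `RDM[i, j] = 1 - Pearson r(pattern_i, pattern_j)`.
#'
#' @param patterns Trial x unit activation matrix (>= 3 trials, >= 2
#'   units).
#' @param source Optional label (model layer or region name).
#' @return An `rdm` object: symmetric matrix with zero diagonal and
#'   entries in `[0, 2]`.
#' @export
compute_rdm <- function(patterns, source = NULL) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 3L || ncol(patterns) < 2L)
    stop("need at least 3 trials and 2 units", call. = FALSE)
  rv <- apply(patterns, 1, stats::sd)
  if (any(rv < 1e-12))
    stop("zero-variance pattern row(s) at trial(s): ",
         paste(which(rv < 1e-12), collapse = ", "), call. = FALSE)
  r <- stats::cor(t(patterns))
  d <- 1 - r
  diag(d) <- 0
  structure(d, class = c("rdm", "matrix"), source = source)
}

upper_vec <- function(m) m[upper.tri(m)]

#' Spearman similarity between two RDMs
#'
#' Spearman correlation of the strictly-upper-triangle entries. If the
#' RDMs carry trial ids of different lengths, the comparison is computed
#' on the trial intersection.
#'
#' @param a,b `rdm` objects or plain square matrices of equal (or
#'   intersectable) size.
#' @param trials_a,trials_b Optional trial-id vectors indexing the rows
#'   of `a` and `b`; when given, both RDMs are subset to the shared ids.
#' @return Spearman rho (scalar).
#' @export
rdm_similarity <- function(a, b, trials_a = NULL, trials_b = NULL) {
  if (!is.null(trials_a) || !is.null(trials_b)) {
    if (is.null(trials_a)) trials_a <- seq_len(nrow(a))
    if (is.null(trials_b)) trials_b <- seq_len(nrow(b))
    shared <- intersect(trials_a, trials_b)
    if (length(shared) < 3L) stop("fewer than 3 shared trials", call. = FALSE)
    a <- a[match(shared, trials_a), match(shared, trials_a)]
    b <- b[match(shared, trials_b), match(shared, trials_b)]
  }
  stopifnot(nrow(a) == nrow(b))
  stats::cor(upper_vec(as.matrix(a)), upper_vec(as.matrix(b)), method = "spearman")
}

#' RSA group and permutation inference
#'
#' Group level: Wilcoxon signed-rank test of the per-subject RDM
#' similarities against zero. Permutation level: the trial labels of the
#' model RDM are jointly permuted over rows and columns, the similarity
#' with each subject's pattern RDM recomputed, and the subject-mean
#' similarity compared with the null;
#' `p = (1 + #[null >= observed]) / (1 + n_perm)`, so the identity
#' ordering is always part of the null.
#'
#' @param patterns List of per-subject trial x unit pattern matrices (one
#'   element also works; the signed-rank test then errors).
#' @param model_rdm The reference `rdm` (e.g. from model layer
#'   activations).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @return List with `rho` (per subject), `mean_rho`, `signed_rank_p`,
#'   `perm_p`, `null` (permutation distribution of the mean rho).
#' @export
rsa_inference <- function(patterns, model_rdm, n_perm = 1000L, seed = 1L) {
  if (is.matrix(patterns)) patterns <- list(patterns)
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values", call. = FALSE)
  subj_rdm <- lapply(patterns, compute_rdm)
  rho <- vapply(subj_rdm, function(r) rdm_similarity(r, model_rdm), numeric(1))
  obs <- mean(rho)
  nt <- nrow(model_rdm)
  null <- with_seed(derive_seed(seed, "rsa_perm"), function() {
    vapply(seq_len(n_perm), function(i) {
      pi <- sample.int(nt)
      mp <- as.matrix(model_rdm)[pi, pi]
      mean(vapply(subj_rdm, function(r) rdm_similarity(r, mp), numeric(1)))
    }, numeric(1))
  })
  sr_p <- if (length(rho) >= 2L) {
    stats::wilcox.test(rho, mu = 0, exact = FALSE)$p.value
  } else NA_real_
  list(rho = rho, mean_rho = obs,
       signed_rank_p = sr_p,
       perm_p = (1 + sum(null >= obs)) / (1 + n_perm),
       null = null)
}

#' Layer-wise RSA against activity patterns
#'
#' Builds an RDM from the requested layer(s) of a trained network
#' (activations z-scored per node across trials by default, to stop
#' high-variance nodes dominating the Pearson distances) and compares it
#' with each subject's pattern RDM.
#'
#' @param params Trained `net_params`.
#' @param data The trials the patterns refer to (`choice_dataset`,
#'   `task_design`, or model-data list).
#' @param patterns List of per-subject trial x unit matrices.
#' @param which Layers to test: any of `"input"`, `"featuremaps"`,
#'   `"hidden"`, `"final"`, or `"all"` (concatenation of every layer).
#' @param scale_nodes Z-score each node across trials before the RDM
#'   (default `TRUE`).
#' @param n_perm,seed Passed to [rsa_inference()].
#' @return Data frame with one row per layer: mean rho, signed-rank p,
#'   permutation p.
#' @export
layerwise_rsa <- function(params, data, patterns,
                          which = c("input", "hidden", "final", "all"),
                          scale_nodes = TRUE, n_perm = 1000L, seed = 1L) {
  if (is.matrix(patterns)) patterns <- list(patterns)
  fw <- net_forward(params, data)
  layer_mat <- function(w) {
    m <- if (w == "all") do.call(cbind, fw$act) else fw$act[[w]]
    if (scale_nodes) {
      m <- apply(m, 2, zscore)
      m <- m[, apply(m, 2, stats::sd) > 1e-12, drop = FALSE]
    }
    m
  }
  out <- lapply(which, function(w) {
    rdm <- compute_rdm(layer_mat(w), source = w)
    inf <- rsa_inference(patterns, rdm, n_perm = n_perm,
                         seed = derive_seed(seed, paste0("layer_", w)))
    data.frame(layer = w, mean_rho = inf$mean_rho,
               signed_rank_p = inf$signed_rank_p, perm_p = inf$perm_p)
  })
  do.call(rbind, out)
}

#' Serialize an RDM to a dense matrix file with JSON header
#'
#' @param rdm An `rdm` object.
#' @param stem Path stem; writes `<stem>.csv` and `<stem>.json`.
#' @param trial_ids Optional trial id vector.
#' @return Invisibly, the paths written.
#' @export
write_rdm <- function(rdm, stem, trial_ids = seq_len(nrow(rdm))) {
  utils::write.table(as.matrix(rdm), paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(source = attr(rdm, "source"),
                            n_trials = nrow(rdm), trial_ids = trial_ids),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(stem, ".csv"), paste0(stem, ".json")))
}
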