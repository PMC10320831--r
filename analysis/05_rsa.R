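#!/usr/bin/env Rscript
# Representational similarity analyses on synthetic multivariate patterns:
# layer-wise RSA against patterns planted from the fitted network's hidden
# layer (the planted layer should win), a control region of pure noise,
# and a sweep over detector counts comparing feature-map representations.
# Expects 03_model_comparison.R to have run.

library(envchoice)

seed <- 1L
fit <- readRDS("scratch/cnn_fit.rds")
cohort <- read_dataset("results/cohort")
d1 <- envchoice:::model_data(cohort, 1L)
sub <- envchoice:::data_subset(d1, 1:100) # one subject's pass, desk scale

fw <- net_forward(fit$full, sub)
hid <- apply(fw$act$hidden, 2, function(x) {
  s <- sd(x); if (s < 1e-12) x * 0 else (x - mean(x)) / s
})
hid <- hid[, apply(hid, 2, sd) > 0, drop = FALSE]

roi <- simulate_neural(hid, list(n_subjects = 12, n_units = 40, noise_sd = 1),
                       seed = derive_seed(seed, "roi"))
ctrl <- simulate_neural(NULL, list(n_subjects = 12, n_units = 40, noise_sd = 1,
                                   n_trials = nrow(hid)),
                        seed = derive_seed(seed, "ctrl"))

layers <- layerwise_rsa(fit$full, sub, roi$patterns,
                        which = c("input", "hidden", "final", "all"),
                        n_perm = 1000, seed = derive_seed(seed, "rsa"))
write.csv(layers, "results/rsa_layers_planted_roi.csv", row.names = FALSE)
message("layer-wise RSA against the planted ROI:")
print(layers)

ctrl_tab <- layerwise_rsa(fit$full, sub, ctrl$patterns, which = "all",
                          n_perm = 1000, seed = derive_seed(seed, "rsa_ctrl"))
write.csv(ctrl_tab, "results/rsa_control_region.csv", row.names = FALSE)
message("control (noise) region: rho = ", signif(ctrl_tab$mean_rho, 3),
        ", permutation p = ", signif(ctrl_tab$perm_p, 3))

# detector-count sweep: feature-map representations of 1..6-detector
# networks compared with the planted ROI patterns
sweep_tab <- NULL
for (k in 1:6) {
  fk <- fit_model("cnn", cohort, folds = 4,
                  seed = derive_seed(seed, paste0("sweep", k)),
                  control = list(config = net_config("cnn", n_detectors = k,
                                                     n_hidden = 16),
                                 epochs = 100, decay = 0.1))
  fmk <- net_forward(fk$full, sub)$act$featuremaps
  fmk <- apply(fmk, 2, function(x) {
    s <- sd(x); if (s < 1e-12) x * 0 else (x - mean(x)) / s
  })
  fmk <- fmk[, apply(fmk, 2, sd) > 0, drop = FALSE]
  rdm <- compute_rdm(fmk, source = paste0("fm_", k))
  inf <- rsa_inference(roi$patterns, rdm, n_perm = 500,
                       seed = derive_seed(seed, paste0("infs", k)))
  sweep_tab <- rbind(sweep_tab, data.frame(
    n_detectors = k, mean_rho = inf$mean_rho,
    signed_rank_p = inf$signed_rank_p, perm_p = inf$perm_p))
}
write.csv(sweep_tab, "results/rsa_detector_sweep.csv", row.names = FALSE)
message("detector-count sweep (feature maps vs planted ROI):")
print(sweep_tab)
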