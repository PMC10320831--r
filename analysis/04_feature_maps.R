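#!/usr/bin/env Rscript
# Decompose the fitted network's decision value into per-detector partial
# DVs, correlate them with the between-environment moment differences, and
# compare the detectors' mean-difference correlations with Steiger's z for
# dependent correlations. Expects 03_model_comparison.R to have run.

library(envchoice)

fit <- readRDS("scratch/cnn_fit.rds")
cohort <- read_dataset("results/cohort")

tab <- partial_dv_table(fit$full, cohort)
mc <- moment_correlations(tab)
write.csv(mc, "results/partial_dv_moment_correlations.csv", row.names = FALSE)
message("per-detector moment correlations:")
print(mc)

# which detector tracks the mean difference most strongly?
rm_ <- mc[mc$moment == "d_mean", ]
lead <- rm_$detector[which.max(abs(rm_$r))]
pdv_cols <- paste0("pdv_", rm_$detector)
out <- NULL
for (d in setdiff(rm_$detector, lead)) {
  r12 <- cor(tab[[paste0("pdv_", lead)]], tab[[paste0("pdv_", d)]])
  z <- compare_dependent_correlations(rm_$r[rm_$detector == lead],
                                      rm_$r[rm_$detector == d], r12, nrow(tab))
  out <- rbind(out, data.frame(lead = lead, other = d, z = z$z, p = z$p))
}
write.csv(out, "results/detector_mean_comparisons.csv", row.names = FALSE)
message("detector ", lead, " leads on mean difference; Steiger z vs others: ",
        paste(round(out$z, 2), collapse = ", "))
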