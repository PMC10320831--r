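#!/usr/bin/env Rscript
# Behavioral analyses of the simulated cohort: the value/bonus-adaptation
# logistic regression (GLM1) on both stages, and the statistical-moment
# regression (GLM2) on environment choice. Expects 01_simulate_task.R to
# have run.

library(envchoice)

cohort <- read_dataset("results/cohort")

g1_env <- fit_glm1(cohort, stage = 1)
g1_item <- fit_glm1(cohort, stage = 2)
g2 <- fit_glm2(cohort)

dump <- function(g, path) {
  write.csv(cbind(coef = rownames(g$group), g$group), path, row.names = FALSE)
}
dump(g1_env, "results/glm1_stage1_group.csv")
dump(g1_item, "results/glm1_stage2_group.csv")
dump(g2, "results/glm2_group.csv")

message("GLM1 (environment choice): EV t = ",
        round(g1_env$group["ev_rl", "t"], 2),
        ", bonus adaptation t = ",
        round(g1_env$group["prob_bon_cond", "t"], 2))
message("GLM2: variance preference t = ",
        round(g2$group["variance_rl", "t"], 2),
        " (the generating agent prefers high-variance environments)")
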