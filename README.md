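# envchoice

Tools for studying **choices between reward environments** — bundles of
twenty probabilistic items shown as probability bars plus one
mean-magnitude number — and the item choices that follow from them, for
computational cognitive neuroscientists who want to develop and validate
the full analysis stack (behavioral regressions, decision-value models,
representational similarity, ROI time courses) without human data.

The core of the package is a model zoo behind one softmax contract
`P(option k) = exp(DV_k / τ) / Σ exp(DV / τ)`:

* a **convolutional network**: 2 × 1 feature detectors slide along the
  20 × 2 item-probability matrix (valid cross-correlation), the feature
  maps — raw and scaled by each option's mean magnitude — are
  concatenated with the bonus and condition flags, pass a ReLU layer, and
  read out into one decision value (DV) per environment;
* "simplified" networks whose input is the environments' mean / variance
  / skewness instead of the full distributions, a dense network for item
  choice, and a sigmoid **autoencoder**;
* parametric models sharing
  `DV = b1·M̂ + b2·P̂ + b3·Bon + b4·Cond + b5·M̂P̂ + b6·(P̂·Bon·Cond)`:
  **mean-variance-skewness** (`P̂ = mean + ρ·var + σ·skew`), **power law**
  (`P̂ = mean(p^g)`), and **cumulative prospect theory**
  (`M̂ = M^α` for gains, `−λ(−M)^β` for losses;
  `w(p) = p^γ / (p^γ + (1−p)^γ)^{1/γ}`, Δ in the loss domain);
* a logistic **decision-value GLM** on the option differences.

Models are compared by 20-fold cross-validated held-out negative log
likelihood with pooled-variance t-tests on the fold values (df = 38 for
two 20-fold fits). Around the zoo sit a deterministic task generator
(exact design proportions), simulated agents with known parameters,
partial-DV feature-map decomposition with Steiger z comparisons, RSA with
signed-rank and permutation inference, and BOLD-style beta time-course,
leave-one-subject-out peak, PPI, and JZS Bayes-factor procedures.

## Worked example

```r
library(envchoice)

task   <- generate_task(task_config(), seed = 1)   # 200 + 200 trials, 400 environments
agent  <- agent_spec("mvs", c(0.5, 0, 1, 5, 0, 0, 1, 2), temperature = 2)
cohort <- simulate_agent(task, agent, n_subjects = 24, seed = 2)

g1 <- fit_glm1(cohort, stage = 1)   # value + bonus-adaptation regression
g2 <- fit_glm2(cohort)              # statistical-moment regression
round(g1$group["ev_rl", "t"], 2); round(g1$group["prob_bon_cond", "t"], 2)
round(g2$group["variance_rl", "t"], 2)
```

prints `30.09`, `6.97`, and `2.73`: the cohort prefers higher-EV
environments (group one-sample t over 24 subjects), adapts its
probability weighting to the bonus only when the bonus is linked to the
gamble outcome (the positive three-way interaction), and prefers
higher-variance environments — the planted moment preference (ρ = 0.5).
Fitting the zoo to the same choices and comparing:

```r
fit_cnn <- fit_model("cnn", cohort, folds = 20, seed = 7,
                     control = list(config = net_config("cnn", n_hidden = 32)))
fit_glm <- fit_model("glm", cohort, folds = 20, seed = 7)
compare_models(list(fit_cnn, fit_glm))$table
```

gives each model's held-out NLL per trial (mean ± SEM over the 20 folds)
and prediction accuracy; `partial_dv_table()` + `moment_correlations()`
then ask which of the network's detectors track which environment
moments, and `layerwise_rsa()` compares layer representations with
(synthetic) multivariate activity patterns.

The numbered scripts under `analysis/` run these stages end to end at
the default task scale and write their tables under `results/`.

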