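---
title: "Modelling choices between reward environments: task, models, and neural analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choices between reward environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most decision research studies *item choice*: picking one of two concrete
probabilistic rewards. This package is about the preceding, harder problem
of *environment choice*: picking between two bundles of twenty
probabilistic items, knowing that the chosen bundle determines which
concrete items one will be offered next. An environment is displayed as
twenty reward-probability bars plus a single number giving the mean reward
magnitude of its items; its value is therefore a *distribution*, and an
agent must compress forty numbers per option into a decision.

The package provides everything needed to study this computationally,
without any human data:

* a generator for the two-stage task (environment choices followed by 0-3
  item choices drawn from the chosen environment),
* simulated agents with known parameters for every model in the zoo,
* the model zoo itself — a convolutional network over the item-probability
  distributions, moment-input "simplified" variants, a dense item-choice
  network, a sigmoid autoencoder, a logistic decision-value GLM, and
  mean-variance-skewness, power-law, and cumulative-prospect-theory
  models — compared by 20-fold cross-validated held-out likelihood,
* a feature-map decomposition ("partial decision values") linking network
  detectors to the statistical moments of the environments,
* representational similarity analysis (RSA) with signed-rank and
  permutation inference, and
* ROI-style BOLD analyses: parametric GLM designs convolved with a
  haemodynamic response function, epoched beta time courses,
  leave-one-subject-out peak statistics with JZS Bayes factors, and PPI
  designs.

## The task generator

`task_config()` defaults reproduce the design constants of the study this
package emulates: 200 stage-1 trials over 400 distinct environments, 200
stage-2 trials (0-3 per block, uniform subject to the total), a
gain/loss/mixed valence mix of 53.5/31.5/15%, a block bonus uniform on
[-4, 6] with a 50/50 linked/unlinked split, item magnitudes within
[-10, 10], and 20 items per environment.

Two generator choices deserve comment because the emulated design does not
pin them down:

* **Item probabilities.** Each environment draws its own Beta shape
  parameters from Unif(0.6, 6) and then its twenty item probabilities from
  that Beta. Environments therefore differ in the location, spread, and
  skew of their probability distributions. This heterogeneity is not a
  nicety: if every environment shared one generating distribution,
  between-environment moment differences would be pure sampling noise and
  moment preferences (ρ, σ) and probability-weighting curvature (γ, Δ)
  would be practically unidentifiable. The exact ranges are configurable
  and not claimed faithful to the original stimuli.
* **Item magnitudes.** A target mean is drawn for each environment (sign
  fixed by its valence), and item magnitudes are mean-zero bounded
  deviations around it, rescaled so every item respects the magnitude
  bound. The displayed mean equals the realized mean exactly.

Proportions (valence mix, linked/unlinked split) are realized by
deterministic largest-remainder allocation, not Bernoulli draws, so the
printed design percentages are exact counts in every generated task. All
randomness flows from one integer seed through labelled sub-streams
(`derive_seed()`); the same seed always yields a byte-identical design.

Trial onsets are laid on a continuous time axis with uniform 4-8 s
inter-trial intervals so that the same dataset can drive the BOLD-like
simulations; the emulated study's actual event timing is not public, and
nothing downstream depends on the specific intervals.

## Decision models

All models share one contract: a trial maps to a pair of decision values
(DV_left, DV_right) and choice probability is `softmax(DV / temperature)`.
The logistic DV-GLM produces a single rightward DV; it is represented as
the pair (0, DV_R), which makes the two-option softmax reduce exactly to
the logistic link.

The parametric models transform each option's magnitude and item
probabilities into subjective quantities and combine them as
`DV = b1*Mag + b2*Prob + b3*Bon + b4*Cond + b5*(Mag*Prob) +
b6*(Prob*Bon*Cond)` (hatted, subjective quantities throughout — the b5
interaction uses the subjective magnitude and probability):

* **MVS**: subjective probability is the mean item probability plus
  ρ·variance + σ·skewness (population moments; skewness of a
  zero-variance option is defined as 0).
* **Power law**: each item probability is transduced by a power g before
  averaging.
* **CPT**: magnitudes pass a power value function with loss aversion λ
  (α for gains, β for losses); probabilities pass an inverse-S weighting
  function with curvature γ (gain options) or Δ (loss options).

Because the bonus and condition are identical for both options, b3 and b4
cancel in the softmax and are unidentifiable from choices; the fitted
models report them as 0. Fitting exploits this: for fixed nonlinear
parameters the identifiable weights enter the DV difference linearly, so
the inner problem is a no-intercept logistic regression solved exactly by
IRLS, and the outer optimizer (bounded L-BFGS-B with an identity start
plus random restarts) searches only the nonlinear parameters. This is the
exact maximum-likelihood estimate of the full model, at a fraction of the
cost of naive 11-parameter optimization.

### The convolutional network

The environment-choice network takes the 20 x 2 item-probability matrix,
slides `n_detectors` (default 4) detectors of size 2 x 1 along the item
axis (valid cross-correlation, stride 1, no padding, no kernel flip),
yielding 19 x 2 feature maps. The concat vector is, in fixed order: the
probability feature maps (flattened item-then-option), the two option
magnitudes, the feature maps scaled by their option's magnitude, the
bonus, and the condition flag. A ReLU layer of `n_hidden` nodes (default
512) feeds a two-node linear readout whose softmax gives the choice
probabilities. The item-choice network ("ann") is the same architecture
without convolution; the "simplified" variants replace the probability
input with the named per-environment moments; the autoencoder uses one
sigmoid hidden layer over ten option features.

Three architectural conventions are the package's own, where the emulated
design is silent:

* **Magnitude interaction**: each option's (standardized) mean magnitude
  scalar-multiplies its column of every feature map.
* **Standardization**: each input channel (probabilities, magnitudes,
  bonus) is z-scored over the training folds; the constants are stored
  with the fit and reused at test time.
* **Label equivariance** (`symmetric = TRUE`): the forward pass is
  averaged with the pass on the option-swapped input (its DVs swapped
  back). Choice probabilities then depend on the options, not on which
  side carries them: identical options receive exactly 0.5, and
  relabelling left/right mirrors all outputs. Networks trained on enough
  data learn this symmetry approximately; building it in makes the
  symmetry properties exact and acts as a free data augmentation.

Training is full-batch Adam on softmax cross-entropy with manual
backpropagation (through both passes when symmetric), optional decoupled
L2 weight decay on the weight matrices, and early stopping on a training
NLL plateau. Defaults (400 epochs, step 0.02) are configurable;
the networks here are small enough that no GPU or framework is needed.

### Cross-validated comparison

`fit_model()` pools choices across subjects, splits trials into 20 random
folds (seeded), and records per-fold held-out negative log likelihood
(both the per-trial mean and the fold sum; comparisons use the per-trial
mean), held-out choice probabilities, and prediction accuracy (probability
of the made choice > 0.5; exact ties count as incorrect).
`compare_models()` reports mean ± SEM per model and pairwise
pooled-variance t-tests on the fold values — df = 38 for two 20-fold
models.

## Partial decision values

`partial_dv()` re-runs the trained network with every other detector's
post-convolution feature maps (probability and magnitude-scaled copies)
set to zero, keeping all trained weights, biases, and the
magnitude/bonus/condition channels. "Discarding" is zeroing, not
retraining, and the fc-layer biases are retained. Partial DV differences
(right minus left) are correlated with between-environment differences in
mean, variance, and skewness; detectors are compared on a shared moment
with Steiger's (1980) z for dependent correlations. With a linear
activation the partial DVs are exactly additive
(Σ_d partial_d − (n−1)·baseline = full DV), which the tests exploit as an
algebraic oracle.

## RSA

An RDM is 1 minus the pairwise Pearson correlation of trial patterns;
two RDMs are compared by the Spearman correlation of their strictly-upper
triangles, so any monotone transform of either RDM leaves the similarity
unchanged. Group inference is a Wilcoxon signed-rank test of per-subject
similarities against zero; permutation inference jointly permutes the
rows and columns of the model RDM, recomputes the subject-mean similarity
per permutation, and reports `p = (1 + #[null >= observed]) / (1 + n_perm)`
— the identity ordering is always part of the null, so p can never be 0.
Default `n_perm = 1000`. When one source lacks trials, the comparison is
computed on the trial intersection. Layer-wise RSA z-scores each node
across trials before computing the model RDM (configurable off) so
high-variance nodes cannot dominate the Pearson distances.

Synthetic "neural" patterns are produced by `simulate_neural()`: the
source representation (any layer's activations) is mixed through a random
semi-orthogonal matrix orthogonal to the constant vector — chosen so the
source's inner-product geometry is preserved *exactly* in the noiseless
limit — plus i.i.d. Gaussian noise per unit.

## ROI time courses

BOLD-like series are design regressors convolved with a canonical
double-gamma HRF (positive lobe peaking at 6 s, undershoot at 16 s at
ratio 1/6, maximum normalized to 1; all configurable) sampled at
TR = 1.6 s, plus AR(1) noise. The four univariate designs mirror the
ROI analyses they emulate: the two-stage DV design with nuisance
regressors; the bonus-split design (basic DV, linked-bonus DV,
unlinked-bonus DV computed as if linked); its stage-2 extension with the
first-item-trial indicator (coded +1/−1) and its interaction with the
linked-bonus DV; and the salience design whose salience
(|EV_L| + |EV_R|) and DV-sum terms use expected value rather than network
DVs, whose normalization discards value signs. Parametric regressors are
mean-centered before convolution.

`beta_timecourse()` upsamples each subject's series tenfold by cubic
spline, epochs it from −2 to +14 s around onsets (covering effect peaks
in the 3-8 s range), and fits an OLS regression across trials at every
upsampled timepoint. `loso_peak()` defines the peak window as the
full-width-half-maximum of the group curve's largest post-onset extremum
and, for each subject, reads the subject's own beta at the extremum
position of the group curve *recomputed without that subject* — the
default reading of the leave-one-subject-out rule; extracting at the
subject's own extremum inside the window is exposed as `rule = "own"`.
Peaks are tested with a one-sample t and a JZS Bayes factor (Cauchy prior
scale √2/2, computed by numerical integration of the standard JZS
marginal likelihood). High-pass filtering and autoregressive noise
modelling are deliberately omitted: the synthetic series match the fitted
model class, and this is a documented limitation for real data.

The PPI design is five columns: the stage indicator (1 = environment
choice), two physiological series, and the stage-by-physiological
interactions with the physiological series mean-centered before
multiplication; a constant stage regressor is flagged as collinear.

## What the tests do and do not show

The test suite and acceptance checks run entirely on synthetic data, so
they establish *internal* correctness and recoverability: oracle
equivalence of the primitives (convolution, RDMs, CPT transforms against
brute-force arithmetic), exact analytic reductions (CPT/power/MVS at
identity parameters ≡ expected value), parameter recovery (CPT α = 0.8,
λ = 2, γ = 0.7 and MVS ρ = 0.5 recovered within ±25% from 5000 simulated
trials across 10 seeds; behavioral GLM coefficients within ±2 SE at
24 x 200 trials), model selection (a trained network out-predicts the
DV-GLM on choices generated by a network with a genuine nonlinear
dispersion preference in ≥9/10 seeds — the generating agent's contrast
and value components are placed on comparable DV scales so the
nonlinearity actually drives choices), RSA calibration (permutation
type-I error within 0.05 ± 0.02 over 500 null runs; planted hidden-layer
structure assigned to the hidden layer), and time-course recovery
(planted amplitudes within ±10% at SNR 5; LOSO peak at a synthetic
bump's center). They do not show that any model fits *human* choices, and
the synthetic BOLD omits scanner drift, motion, and physiological
artifacts. Problem sizes in the tests (e.g. 8-16 hidden nodes, 12-25
simulated subjects) are desk-scale choices; the full-scale network
(512 nodes) is one config knob away and used in the analysis scripts'
documentation.

## Numerical conventions

* Population (÷n) moments everywhere; sample moments by flag in the
  behavioral GLMs.
* Behavioral GLM regressors are z-scored within subject by default
  (interactions formed first); raw scale by flag. Perfect separation is
  detected and the subject excluded with a warning, never silent ±∞.
* Softmax is computed with max-subtraction; likelihoods floor
  probabilities at 1e-12.
* CPT curvatures are bounded to (0.2, 1.5] and value powers to (0.2, 2]
  to keep the transforms monotone and the likelihood finite.
* Accuracy ties (probability exactly 0.5) count as incorrect.
* All percentages printed by the generator are exact by deterministic
  allocation.
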