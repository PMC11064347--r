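---
title: "Predicting 1-sd classes of cardiovascular risk factors from multi-omic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 1-sd classes of cardiovascular risk factors from multi-omic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateomix)
```

## The problem

Continuous cardiovascular risk factors — systolic and diastolic blood
pressure (SBP, DBP, mmHg) and three echocardiographic indices of left
ventricular diastolic dysfunction (E/e' ratio, E/A ratio, and the left
atrial volume index LAVI, mL/m²) — are clinically interpreted through
thresholds. `lateomix` casts each of them as a three-class problem: samples
deviating from the training mean by more than one training standard
deviation downwards (class −1), upwards (class +1, the at-risk group), or
lying within one sd (class 0). With approximately Gaussian risk factors
this produces a ~15/70/15 class imbalance, so evaluation uses the macro-F1,
the unweighted mean of the three one-vs-rest F1 scores; it rewards models
for the rare deviant classes. A predictor that draws labels with the class
prevalences has expected macro-F1 of exactly 1/3 regardless of the
prevalence vector, which anchors every comparison.

The predictors are three omic blocks of very different widths —
transcriptomic intensities (thousands of probes), metabolomic
concentrations (hundreds), and methylation beta values in (0,1) (a small
literature-derived CpG panel) — plus age, sex and BMI.

## Pipeline overview

1. **Preprocessing** (training-sample statistics only): targets are
   residualized on age, sex and BMI by OLS and z-scored (these adjusted
   targets supervise the autoencoders; 1-sd classing always uses the raw
   targets). Transcriptomic features are kept when they correlate with an
   adjusted blood-pressure target (two-sided Pearson nullity test,
   p < 0.05) or with an adjusted diastolic-function target while exceeding
   a raw training variance of 0.01. Transcriptomic features are min-max
   scaled, metabolomic features z-scored, methylation beta values kept
   untouched.
2. **Semi-supervised autoencoding**: each wide block is reduced by a
   denoising autoencoder whose bottleneck is additionally supervised by a
   one-layer-perceptron head predicting the five adjusted targets.
3. **Variable importance**: the Connection-Weights (Olden) product of the
   encoder and head weight matrices.
4. **Classification**: a six-family classifier bank on each encoded block
   (plus covariates), tuned by stratified 5-fold cross-validation on
   macro-F1.
5. **Late integration**: per-omic class probabilities are fused through a
   cross-omics probability tensor and a small View Correlation Discovery
   Network (VCDN).
6. **Transfer learning**: the pre-trained encoder is reused for binary
   hypertension prediction in a distribution-shifted external cohort and
   compared with an identically shaped model trained from scratch.

## The semi-supervised autoencoder

The network is `dropout(r)` on the input, a dense LeakyReLU layer of width
`p`, a LeakyReLU bottleneck of width `l`, a symmetric LeakyReLU decoder
with a linear output of width `p_in`, and a grafted head
`dense(l, LeakyReLU) -> dense(t, linear)`. Inputs are corrupted with fresh
Gaussian noise every epoch and the model reconstructs the *original* data,
the classic denoising objective. The two outputs share one loss,

$$L = \alpha\,\mathrm{MSE}(X, X') + (1-\alpha)\,\mathrm{MSE}(Y, Y'),$$

with the convexity parameter $\alpha \in [0,1]$; $\alpha = 1$ is a plain
unsupervised autoencoder (USAE) and $\alpha = 0$ pure target regression.
Each MSE is the mean over all matrix elements (not a per-sample sum), so
reconstruction caps are comparable across blocks of different widths.
Optimization is mini-batch Adam (batch 64, learning rate $10^{-3}$,
per-epoch multiplicative decay 0.9 by default) with early stopping: after
a minimum epoch count, training stops when the validation loss fails to
improve the mean over the preceding `stop_window` epochs. One fifth of the
training partition is held out as the validation sample.

Defaults mirror the study settings for reproducing its chosen models:
transcriptomic `p = 150, l = 50`, metabolomic `p = 55, l = 6`,
`alpha = 0.9`, dropout `r = 0.5`, corruption sd 0.01 (min-max-scaled
transcriptomic data) and 0.1 (z-scored metabolomic data) — about a tenth
of the mean feature sd in each case. At the small synthetic sizes used in
the examples and tests, the default learning rate and decay learn too
slowly to be informative, so those runs pass explicit controls (learning
rate $10^{-2}$, decay 0.98, proportionally longer minimum epochs); the
defaults themselves are untouched.

Design choices the architecture description leaves open, and how this
package resolves them: the head's hidden layer has the bottleneck width
`l`; dropout is applied only to the input layer and disabled at inference;
the LeakyReLU slope defaults to 0.1; the stopping statistic is the total
bi-output validation loss; corruption is resampled every epoch.

### The matched unsupervised control

Comparing SSAE and USAE subspaces is only fair at equal reconstruction
quality, so `train_usae_matched()` trains the control until its validation
reconstruction MSE first reaches the paired SSAE's final value and then
stops (an explicit error if it never does). Architecture search
(`select_architecture()`) keeps the candidate with the fewest parameters
whose reconstruction MSE and mean absolute bottleneck correlation respect
per-omic caps (0.015 / 0.25 and 0.4 / 0.3 for transcriptomic /
metabolomic data), breaking ties toward the smaller bottleneck.

## Connection-Weights importance

`connection_weights()` multiplies the encoder and head weight matrices,
`RI = W1 W2 H1 H2`, excluding biases and activations, which preserves the
sign of each feature's contribution. With linear activations this is
exactly the network's input-to-output Jacobian — the package verifies this
against central finite differences. Scores are z-scored per target for
ranking tables, and focus panels (e.g. literature-reported genes) are
located by the percentile of their absolute importance.

## Classifier bank and late integration

The six families — random forest, linear and RBF SVM, LDA, gradient
boosting, and a one-hidden-layer MLP — are standard algorithms from
established R packages behind one fit/predict-probability contract; the
package's contribution is the stratified cross-validated tuning on
macro-F1, the out-of-fold probability plumbing, and the leakage audit.
Tuning grids are small and explicit; SVM probabilities come from pairwise
coupling and every probability row is normalized to the simplex. Hard
labels break exact probability ties toward the middle class, a
deterministic rule that matters only on degenerate inputs.

For fusion, each sample's per-omic probability vectors are combined into a
Cross-omics Discovery Tensor: with $m$ omics and $c$ classes, every entry
is a product of one class probability per omic, giving $c^m = 27$ entries
for three omics and three classes. Before rescaling the entries sum to one
whenever the inputs do (the product of the row sums), an identity asserted
on every construction. The undefined "rescaling" is resolved as
multiplication by $c^m$, which gives a uniform tensor unit entries and
keeps early-training gradients well-scaled; the factor is recorded and
configurable. The VCDN is a fully connected net $c^m \to c^2 \to c$ with
LeakyReLU hidden activation, softmax output and cross-entropy loss — the
loss and output map are not specified by the method description and are
the standard choice. VCDNs are trained on *out-of-fold* training
probabilities so the meta-learner cannot exploit classifier overfit, one
instance per target and classifier family. The omic order is fixed
(transcriptomic, metabolomic, epigenetic) and the flattening convention
(first omic slowest) documented for reproducibility.

## Transfer learning

`build_transfer_model()` copies a trained encoder (frozen thereafter) and
grafts a task head: dropout on the bottleneck, a task-specific hidden
layer (default width `l`), concatenation with age, sex and BMI, and a
logistic score trained with binary cross-entropy. Because the encoded
activations are not centered, a fixed affine normalization of the
bottleneck — statistics taken once from the fine-tuning samples when
fine-tuning starts — sits between encoder and head in both arms; without
it the head optimizes poorly. The scratch clone has identical topology
with all layers trainable and freshly initialized. Within a repeat both
arms see the same fine-tune/evaluation split and batch order, a paired
design. Hypertension is labelled by the clinical rule SBP > 140 mmHg OR
DBP > 90 mmHg (strict inequalities; the conjunctive reading is available
via `rule = "and"`). The external block is scaled with its own
fine-tuning-subset statistics, matching the scaling convention of the
source omic, since the external cohort is preprocessed independently.

## The synthetic cohort generator

The study cohorts are access-restricted, so `simulate_cohort()` provides a
latent-factor linear-Gaussian stand-in reproducing the only structure the
methods rely on: a configurable number of shared standard-normal latent
factors load a `signal_density` fraction of each block's features (one
latent per signal feature, magnitude U(0.4, 1.2), random sign); targets
combine latents, additive covariate effects and Gaussian noise, rescaled
so each target matches typical population means and sds (SBP 119 (14.2),
DBP 75.2 (10.6), E/e' 4.8 (1), E/A 1.5 (0.4), LAVI 22.5 (6.6)), which
yields the ~15/70/15 class splits; methylation values are inverse-logit
squashed Gaussians, strictly in (0,1); default block widths 2000/200/75
echo the study's 5842/228/75 at desk scale. Samples split 80/20 into
training and test with a fifth of training flagged validation.

`simulate_external_cohort()` reuses the same latent structure and loadings
(so transferring an encoder is meaningful) and applies the configured
shifts: age +21 years, SBP +32 mmHg, DBP +10 mmHg (defaults landing at an
FTC-like mean age 62.5 and SBP ≈ 151), mild oversampling of hypertensive
candidates, and per-feature additive and multiplicative (log-normal,
hence strictly positive) batch effects — on the logit scale for the
methylation block. Covariates are standardized around the external
cohort's own means so that the demographic offsets do not mechanically
re-shift the targets; the mmHg offsets are the explicit controls. Only
SBP/DBP are populated externally. The generator draws samples
independently: it does not emulate twin-pair dependence, missing data, or
medication-use correction, and passing tests on it show that the
*machinery* behaves as specified, not that real cohorts would reach any
particular performance.

## Leakage discipline

Every preprocessing statistic — adjustment coefficients, filter
correlations, scaling statistics, class boundaries, subspace scaling —
derives from samples flagged `train` only; the validation fifth steers
early stopping and never enters those statistics. Each preprocessing
object records the sample ids it used, and `audit_leakage()` asserts they
are exactly the training samples; `run_full()` performs these audits on
every run. Out-of-fold probabilities record their fold assignment so a
sample's own fold model is verifiably never used.

## Benchmark problem sizes and numerical choices

The test suite and the acceptance script exercise the directional claims
at sizes chosen for a desk-scale machine, fixed once as the package's
benchmark conditions:

- *Semi-supervision benefit*: 20 replicates of planted data (n = 360, 40
  features) where the target-relevant latents carry little block variance;
  paired SSAE (α = 0.5) and matched USAE, LDA on the bottleneck, macro-F1
  on held-out samples.
- *Late-integration benefit*: 20 replicates of three 8-feature blocks each
  observing one of three latents whose sum drives the target; per-omic LDA
  probabilities fused by a VCDN.
- *Transfer benefit*: five meta-replicates of 10 repeats over fine-tuning
  fractions 0.2–0.8 on a 1000-feature transcriptomic-style block. The
  source SSAE here uses α = 0.3, bottleneck 8, and at least 80 epochs:
  the transfer mechanism requires a pre-trained encoder that actually
  captured the blood-pressure latents, and with weak supervision or very
  early stopping the synthetic encoder only does so for some seeds.

Numerical conventions: sample (n−1) standard deviations throughout;
values at exactly one sd belong to the middle class (the deviant classes
require strictly more than one sd); zero-variance features are excluded
from correlation filtering with a message; F1 is 0 for a class with no
true or predicted members (with a warning when absent from both); AUC
ties count one half; probability rows are renormalized to the simplex
before use; all stage seeds derive deterministically from one global seed
and a stage name.

## Limitations

The generator's linear-Gaussian structure is favourable to linear
encoders; nonlinear omic-target relations, heavy-tailed measurement
error, twin dependence and batch structure beyond per-feature
location/scale are out of scope. Absolute macro-F1 or AUC values on
synthetic cohorts say nothing about attainable performance on real
cohorts; only the directional comparisons (semi-supervised vs matched
unsupervised, fused vs single-omic, transfer vs scratch) are meaningful,
and those are what the package asserts.
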