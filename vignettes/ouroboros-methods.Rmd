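---
title: "Generative-predictive modelling of histology and spatial protein expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative-predictive modelling of histology and spatial protein expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Imaging mass cytometry measures the expression of a few dozen protein
markers at cellular resolution on one tissue section, while a consecutive
section is H&E-stained and scanned as a whole-slide image (WSI). Pairing the
two yields, for every 128×128 px *spot* of the slide, a marker expression
vector **p** and a 256×256 px image patch **I** centred on the spot. This
package models that pairing in both directions with one adversarial system:

* a conditional **generator** `I-hat = G(p, z; theta_G)` that renders an
  H&E-like patch from an expression vector and Gaussian noise `z ~ N(0, I)`;
* a dual-head **discriminator** `D(I; theta_D)` that emits a realism logit
  *and* a predicted expression vector `p-hat`, so the same trunk that judges
  real vs. generated images also solves image-to-expression regression.

Training both directions jointly is the point: the prediction head is
regularised by the adversarial game, and the generator can be probed with
counterfactual expression vectors (perturbation and interpolation
experiments) to ask how histology responds to marker changes.

## Losses and their assignment to players

Four terms are combined, `L = L_I + lambda1 L_r + lambda2 L_p +
lambda3 L_GAN`, with defaults `lambda1 = 1`, `lambda2 = 1`,
`lambda3 = 0.01`:

* `L_I` — mean absolute error between the ground-truth patch and the patch
  generated from its expression vector (fresh `z` every step);
* `L_r` — mean squared error between `p` and the prediction from the
  *generated* image; it back-propagates through a frozen discriminator into
  the generator;
* `L_p` — mean squared error between `p` and the prediction from the *real*
  image; it trains the discriminator's prediction head;
* `L_GAN` — the standard min-max adversarial value; the discriminator
  maximises `log s(D(I)) + log(1 - s(D(G(p, z))))` (s = sigmoid).

The composite objective mixes terms owned by different players, so each
update minimises only the terms its parameters influence: the generator
takes `L_I + lambda1 L_r + lambda3 L_GAN_g`, the discriminator
`lambda2 L_p + lambda3 L_GAN_d`, one update each per step (1:1 schedule).
For the generator's adversarial part the non-saturating surrogate
`-log s(D(G))` is the default (the literal min-max form is selectable with
`generator_loss = "saturating"`); both push the fake logit in the same
direction, but the non-saturating form keeps gradients alive early in
training. Optimisation is Adam with learning rate `1e-4`, first-moment
decay `0.5`, batch size 16. Loss decomposition is asserted at every step:
reported totals always equal the lambda-weighted sums of the logged parts.

## Architecture

Both networks are size-configurable through one descriptor
(`nn_arch(patch_size_px, n_markers, noise_dim, base_width)`); the number of
up/down-sampling stages `s` satisfies `4 * 2^s = patch_size_px`, so the same
code instantiates 16 px test models, the 64 px desk-scale default and a
256 px paper-scale model.

The generator starts from a learned 4×4 seed computed from `[z; p]`,
followed by `s` residual blocks. Each block normalises with **conditional
instance normalisation** — per-sample, per-channel normalisation whose gain
and bias are affine functions of the stage's conditioning vector
(`gamma = 1 + [p; z_i] W_g`, `beta = [p; z_i] W_b`, where `z_i` is the
stage's chunk of the noise vector) — so the expression vector conditions
every stage and the noise is injected hierarchically, as in the BigGAN
family the design follows. Each block then
convolves twice (3×3, bias-free: a bias before normalisation receives an
identically zero gradient) and up-samples by nearest neighbour at the end
of the block; the skip path is a 1×1 convolution plus the same up-sampling.
Running the convolutions at the pre-upsample resolution and placing the
single nonlocal self-attention block at the 8×8 feature map (rather than
the 1/4-resolution map) are deliberate deviations from the BigGAN-style
reference layout: they cut the per-step CPU cost several-fold while keeping
the residual + attention structure, which is what matters at this scale.
The attention residual gain is initialised at 0.1 instead of 0 so every
attention parameter receives gradient from the first step. The output
stage is instance norm → ReLU → 1×1 projection to RGB → a fixed 3×3
binomial antialiasing filter (exact adjoint used in the backward pass) →
tanh, producing values in [-1, 1].

The discriminator mirrors the design: a 3×3 stem, `s` residual blocks that
pool then convolve (no normalisation), self-attention at the 8×8 map, global
sum pooling (the BigGAN convention; sum pooling also scales the gradients
that flow back into the generator through the adversarial and
expression-reconstruction terms, which mean pooling was found to starve),
and two linear heads — a scalar realism logit and an `n_markers`
regression. It consumes full patches; evaluation-time spot
cropping is an explicit evaluation step, not part of the model.

All forward/backward passes are hand-written (R orchestration over
Rcpp/Armadillo kernels for convolution im2col/col2im, instance norm,
pooling and the antialiasing filter) and validated against central finite
differences to ~1e-7 relative error in the test suite. Training is
bit-reproducible on CPU given the seeds, which are all derived from one
run seed and logged.

## Preprocessing

**Zero-aware log/z transform.** Per marker, nonzero raw values map to
`(log x - mu)/sigma` with `mu`, `sigma` estimated from that marker's
nonzero log values only. Zeros are mapped through the same affine map
applied to a pseudo-count 1000× smaller than the marker's smallest observed
positive value, which places them strictly below every transformed nonzero
value: zeros act as a separate "not expressed" category rather than a point
on the positive scale. Two readings of the "factor of 1000" were possible
(dividing the per-marker minimum positive value, or a global constant); the
per-marker minimum was chosen because it keeps the sentinel on each
marker's own scale, and the sentinel is excluded from `mu`/`sigma` so it
cannot distort them. Degenerate markers are handled explicitly: a single
distinct nonzero value falls back to `sigma = 1` (warning); an all-zero
marker maps to the documented floor value −10 (warning). The fitted state
(per-marker `mu`, `sigma`, minimum positive value, sentinel factor) is
serialisable as JSON and reusable on held-out data, so cross-validation
folds never leak test statistics.

**Batch correction.** Patient-to-patient location/scale shifts are removed
with a self-contained implementation of the parametric empirical-Bayes
scheme used by the ComBat family: standardise each marker by the
batch-size-weighted grand mean and pooled variance, estimate per-batch
additive and multiplicative effects, shrink them toward common normal /
inverse-gamma priors by the usual iterative EB solution, remove them and
restore the overall location and scale. Covariates are not modelled (the
design has none). After adjustment the per-marker grand mean is restored
exactly — the EB estimates leave a sub-0.01 residual shift, and pinning the
grand mean makes the "location restored" contract testable at 1e-6. A
single batch is returned unchanged; a zero-variance marker within a batch
falls back to a scale effect of 1 with a warning. The implementation is
cross-checked against `sva::ComBat` in the test suite.

**Fold preprocessing.** Under leave-one-patient-out cross-validation the
transform and the batch correction are fitted on training patients only.
The held-out patient is a batch never seen in training, so its correction
cannot come from the EB fit; it is aligned by per-marker location/scale
moment matching to the corrected training distribution. This uses only the
held-out patient's own unlabelled moments — no training labels and no
test-into-train leakage — and mirrors how a frozen pipeline would absorb a
new batch.

## The synthetic cohort simulator

No real accession is bundled, so every downstream stage is exercised on a
simulator whose *structure* mimics Hyperion/H&E pairs and whose *causality*
is known. Four designated markers drive morphology:

* **density** — nucleus count per patch, a logistic response between
  `k_range` (3–28 nuclei on a 64 px patch, scaled by patch area);
* **size** — mean nucleus radius, logistic between 3.5% and 8% of the patch
  side;
* **hema** — nuclear darkness, interpolating fixed RGB anchors from light
  (0.62, 0.52, 0.75) to dark blue-purple (0.20, 0.10, 0.42);
* **eos** — background pink, white (0.97, 0.95, 0.96) to eosin pink
  (0.91, 0.58, 0.70), over a low-frequency multiplicative texture.

Driver latents are standard normal; the other 34 markers are fixed linear
mixtures of the drivers plus independent noise, giving realistic marker
correlation without new mechanisms. Counts are gamma-mixed Poisson
(negative-binomial-like, `variance = mu + 0.4 mu^2` by default) around
`exp(1 + latent + patient_shift)`, so zeros arise naturally at low means;
the per-patient shift is a fixed N(0, 0.3²) offset per marker on the log
scale, which makes patient identity linearly decodable from raw expression
and removable by the batch correction. Per-cell count vectors (one per
rendered nucleus) average to the spot expression through `aggregate_spot()`.

Dense tissue is rendered *crowded*: the minimum centre spacing shrinks and
the mean radius contracts (factor `1.25 - 0.5 * sigmoid(density)`) as the
density driver rises, as in real hypercellular tumour regions. This matters
for identifiability: the 63-feature morphology vector is a per-nucleus
average and would otherwise carry no density information at all; crowding
lets density leave a per-nucleus signature (smaller, touching, less convex
nuclei) while counts remain the primary readout. These defaults were chosen
once as the package's study conditions and are validated by property tests
(detected count vs. density rank correlation ≥ 0.8; ridge recovery of
density and size from morphology at held-out r ≥ 0.7).

What the simulator does **not** emulate: real chromatin texture, cell-type
mixtures, spatial neighbourhood interactions, stain variation between
slides, and registration error between consecutive sections. Passing the
acceptance suite therefore demonstrates that the pipeline's machinery is
correct and that the model can learn genuine causal expression–morphology
couplings at desk scale — not that it reproduces GBM histology.

## Evaluation

**Spot cropping.** All quantitative image metrics are computed on the
central spot crop (half the patch side), because expression is defined at
spot resolution; crops use half-open, axis-centred bounds.

**Image distance.** Frechet distance between Gaussian fits of embedded
image sets, `||mu_A - mu_B||^2 + Tr(S_A + S_B - 2 (S_A S_B)^{1/2})`, with
the trace term computed from the eigenvalues of `S_A S_B` and a small
diagonal regulariser for near-singular covariances. The default embedding
is a fixed, seeded 3-layer random convolutional network (64 dimensions:
global mean and standard deviation of the last feature map); random
convolutional features are a standard lightweight surrogate when a
pretrained embedding cannot be shipped, and values are comparable only
within one embedding and seed. A documented 21-feature handcrafted
embedding is available, and `external_pretrained` is an explicit error
explaining that it would require a download. The generated-vs-real distance
is always reported next to the uniform-noise-vs-real distance from the same
embedding, mirroring how the original analysis anchors its scale.

**Nucleus detection and morphometry.** A classical detector replaces
trained-weight segmenters: colour deconvolution with the standard
Ruifrok–Johnston H&E optical-density matrix, Gaussian smoothing (sigma 1 px)
of the haematoxylin channel, Otsu threshold, 3 px morphological opening,
distance-transform watershed to split touching nuclei, and an area filter
that scales with patch area. Each patch yields a 63-feature profile:
9 shape descriptors (area, perimeter, equivalent diameter, major/minor
axis, eccentricity, solidity, extent, circularity) and 9 order statistics
(mean, sd, min, max, median, 10th/90th percentile, skewness, kurtosis) of
6 intensity channels (R, G, B, haematoxylin, eosin, optical density) over
nuclear pixels, averaged across the patch's nuclei. The exact feature list
of the original QuPath-based analysis is not published; this set is a
faithful stand-in covering the same size/solidity/stain-distribution
categories, not a bit-level match. A patch with no detected nuclei yields a
flagged (NA) vector excluded from distance computations.

**Paired morphological test.** Per real patch, the standardized Euclidean
distance to its matched synthetic counterpart is compared with its mean
distance to 100 random real patches of the same WSI (sampling without
replacement when the pool allows, else with replacement), then a one-sided
Wilcoxon signed-rank test asks whether matched distances are systematically
smaller. The per-feature scaler comes from the real reference set. The test
suite checks the p-value against an exact sign-pattern enumeration oracle
and verifies the ~5% false-positive rate under shuffled pairing.

**Prediction metrics.** Per-marker Pearson and Spearman correlations with
p-values across spots; constant columns are recorded as missing and
excluded from means with their count reported. The prediction-only
baseline is a residual CNN regressor from the same size-configurable
family, trained with MSE only under the identical cross-validation folds —
the comparison the dual-head hypothesis needs.

## Perturbation, interpolation and subspace alignment

`interpolate_expression()` builds the exact affine path
`v_i = (1 - t_i) p_a + t_i p_b`, `t_i = i/(steps - 1)`; "ten steps" is read
as 10 vectors including both endpoints (matching the ten panels such
experiments display; the count is configurable). During image generation
the noise vector is held fixed across steps by default so image changes
reflect expression changes only. `perturb_expression()` shifts a single
marker in transformed space; perturbations commute.

Alignment between expression and generated-image morphology is quantified
with a regularized CCA (columns standardized internally, ridge
`1e-4 × mean diagonal` on both covariances, canonical correlations clamped
to [0, 1] and non-increasing), followed by a k = 8 full-covariance Gaussian
mixture on the 2-D morphology projection. The original analysis makes this
claim visually; here it is made testable by fitting an independent mixture
on the expression projection and scoring the two partitions with the
adjusted Rand index.

## Problem sizes and numerical choices

The package's study conditions are a four-patient cohort of 400 spots each
at 64×64 px (spot 32 px), leave-one-patient-out fold 1, 12 epochs
(~900 steps at batch 16) — sizes at which the full pipeline trains in
minutes on one CPU core while leaving every effect measurable. The
acceptance script runs the same pipeline at 250 spots per patient and 10
epochs. Checkpoint selection is by validation mean Pearson r of the
prediction head on a 10% split of the training spots (epoch count and
early-stopping were not fixed by the original description; they are
configuration here). Numerical details: adversarial losses are evaluated in
softplus form; instance norm uses eps 1e-5; Adam uses beta2 0.999,
eps 1e-8; FID clamps negative eigenvalues and the final value at 0; CCA
whitening floors eigenvalues at 1e-12; the GMM falls back to seeded k-means
initialisation if EM degenerates (logged).

## Known limitations

* The renderer's simplicity means image realism is only meaningful relative
  to the simulator's own distribution; FID values here say nothing about
  real H&E.
* MAE-driven generation with fresh noise favours conservative, smooth
  layouts on held-out expression vectors; nucleus placement diversity comes
  only from the weak adversarial term at `lambda3 = 0.01`. At the
  desk-scale step budget (roughly one to two thousand Adam updates at
  learning rate 1e-4) the generator reliably matches the global colour and
  texture statistics of the target distribution — embedded-space distances
  sit far below the noise reference and generated-image morphology aligns
  strongly with expression under CCA — but discrete, countable nuclei
  emerge only partially: the detected nucleus count in generated patches
  stays below the real count and tracks the density driver only weakly.
  Per-patch paired morphological matching and interpolation count sweeps
  therefore under-perform at this budget; they are properties of the
  long-run adversarial equilibrium, not of the first couple of thousand
  steps. The loss balance is the published one; extending training is the
  remedy, not re-weighting.
* The empirical-Bayes batch correction shrinks per-marker batch effects
  toward the common prior, so individual markers retain residual
  between-batch mean differences of a few hundredths even at 500 spots per
  batch — exactly as the reference implementation does; only the average
  residual is driven well below that.
* The discriminator carries no spectral or gradient penalty; stability at
  this scale comes from the small learning rate and the strong supervised
  terms. Paper-scale 256 px training would likely need one.
* The held-out-batch alignment (moment matching) assumes the new patient
  differs from the pooled training distribution by location/scale only —
  exactly the simulator's batch model, and an approximation anywhere else.
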