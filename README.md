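# ouroboros

Generative-predictive modelling of H&E histology and spatial protein
expression in R.

Spatial proteomics (e.g. the Hyperion imaging mass cytometer) measures
dozens of protein markers per cell on one tissue section while a
consecutive section is H&E-stained and scanned. Pairing the two gives every
128×128 px *spot* of the slide an expression vector **p** (38 markers by
default) and a larger context patch **I** centred on it. This package
trains a single adversarial system that links the two directions at once:

* a conditional generator `Î = G(p, z; θ_G)` renders an H&E-like patch
  from an expression vector and Gaussian noise `z ~ N(0, I)`;
* a dual-head discriminator `D(I; θ_D)` scores realism **and** predicts
  the expression vector `p̂` from an image.

Training minimises `L = L_I + λ₁L_r + λ₂L_p + λ₃L_GAN` (MAE image
reconstruction; MSE expression reconstruction from generated images; MSE
expression prediction from real images; the min-max adversarial value),
with λ₁ = 1, λ₂ = 1, λ₃ = 0.01, Adam (lr 1e-4, β₁ 0.5), batch 16, under a
leave-one-patient-out protocol. Because the generator is conditional, the
fitted model supports counterfactual experiments: perturb or interpolate
expression vectors and watch the rendered morphology respond.

The package is fully self-contained: preprocessing (spot aggregation, a
zero-aware log/z transform, empirical-Bayes batch correction), the GAN core
(hand-written forward/backward passes over Rcpp/Armadillo kernels — no
deep-learning framework required), quantitative evaluation (Frechet image
distance with a seeded embedding, classical nucleus detection, a 63-feature
nuclear morphometry profile, paired distance tests, per-marker correlation
metrics, a prediction-only CNN baseline), interpolation/perturbation
experiments, CCA subspace alignment with GMM concordance scoring, and a
multi-patient tissue simulator with known causal structure so everything
runs end-to-end without real data.

## Worked example

Simulate a small two-patient cohort, fit the model, and inspect it:

```r
library(ouroboros)

scfg <- sim_config(n_patients = 2, spots_per_patient = 150,
                   patch_size_px = 32, seed = 1)
ds   <- simulate_cohort(scfg)
cfg  <- run_config(patch_size_px = 32, spot_size_px = 16, epochs = 10,
                   marker_names = ds$marker_names, seed = 1)
fit  <- ouroboros_fit(ds, cfg)
print(fit)
#> Generative-predictive expression/histology model
#>   patch 32 px, 38 markers, 300 training spots (2 patients)
#>   best epoch 7 (validation mean Pearson r = 0.223)
```

The validation line tracks the discriminator prediction head; a couple of
minutes of training on 300 toy spots recovers a first slice of the
expression signal (the desk-scale runs below go much further). Predict
expression for new patches, generate patches for new expression, and sweep
an interpolation path:

```r
p_hat <- predict(fit, ds)               # spots x 38, transformed space
imgs  <- simulate(fit, seed = 2,        # H x W x 3 x n array in [0, 1]
                  expression = predict(fit, ds)[1:4, ])

sweep <- run_interpolation_experiment(fit$gen,
           p_a = fit$train_expression[1, ],
           p_b = fit$train_expression[2, ], steps = 10, seed = 3)
head(sweep$morphology, 4)               # nucleus count / area per step
#>   step n_nuclei mean_area
#> 1    1        1        39
#> 2    2        1        36
#> 3    3        1        17
#> 4    4        2        27
```

At the package's study scale (4 patients × 400 spots at 64 px,
leave-one-patient-out, ~900 steps) the prediction head reaches a held-out
mean Pearson r ≈ 0.65 across the 38 markers versus ≈ 0.49 for a
prediction-only CNN baseline trained with the same budget — the dual-head
advantage the method is built around. Generated patches sit far closer to
real ones than a uniform-noise reference in embedded-image distance, and a
CCA of true expression against generated-image morphology shows strongly
aligned subspaces; the methods vignette discusses which generation
properties need training budgets beyond desk scale.

A thin CLI wraps the same functions
(`inst/cli/ouroboros simulate|preprocess|train|evaluate|interpolate|align`).

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ouroboros",
                               load_package = "installed")'
```

Unit tests cover each module against analytic and brute-force oracles
(finite-difference gradient checks of the entire backward pass, exact
signed-rank enumeration, closed-form Frechet distances, `sva::ComBat`
cross-checks); `test-acceptance.R` runs the full desk-scale training fold
and asserts the end-to-end properties above, so the suite takes roughly
20 minutes on one CPU core.

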