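Package: ouroboros
Title: Generative-Predictive Modelling of Histology Images and Spatial Protein Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-links spatial protein expression with haematoxylin-and-eosin
    (H&E) tissue morphology through a conditional generative adversarial
    network: a generator synthesises H&E-like image patches from spot-level
    protein expression vectors while a dual-head discriminator scores realism
    and predicts expression from images. Includes spot-level aggregation of
    per-cell marker counts, a zero-aware log/z-score expression transform, an
    empirical-Bayes location/scale batch correction, leave-one-patient-out
    training and evaluation (Frechet distance on image embeddings, nuclear
    morphometry with a classical H&E nucleus detector, paired morphological
    distance tests, per-marker correlation metrics), expression interpolation
    and perturbation experiments, canonical-correlation subspace alignment
    with Gaussian-mixture concordance scoring, and a synthetic multi-patient
    tissue simulator so the whole pipeline runs end-to-end without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    tiff,
    yaml,
    jsonlite,
    mclust,
    e1071,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sva,
    MASS,
    withr
Config/testthat/edition: 3
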