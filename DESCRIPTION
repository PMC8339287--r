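Package: irtfuse
Title: Latent Trait Measurement by Fusing Item Response Theory and Text-Derived Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graded response model (GRM) estimation for polytomous Likert
    questionnaires, with item parameters fitted either by a deterministic
    Bock-Aitkin EM algorithm or by Metropolis-Hastings Robbins-Monro (MH-RM)
    stochastic approximation, and latent traits scored by maximum a posteriori
    (MAP) estimation on a bounded grid. A companion text pipeline turns
    per-subject free-text documents into row-normalised TF-IDF features,
    selects features by univariate F tests, trains a calibrated linear
    support-vector classifier and emits a per-subject log likelihood-ratio
    score. The two sources are fused in a Bayesian scheme in which the text
    score defines a person-specific normal prior for trait estimation; the
    fused features are classified with Gaussian naive Bayes. Includes
    threshold rules for dichotomising traits, stratified cross-validated
    confusion-matrix evaluation, an end-to-end study runner, and a synthetic
    data generator emulating the assumed data structure.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
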