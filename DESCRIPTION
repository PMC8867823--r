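Package: codak
Title: Kernel Distance Covariance Tests for Compositional Cell-Type Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association testing between compositional cell-type abundance
    profiles (e.g. clustered mass cytometry data) and categorical or
    continuous predictors using kernel distance covariance on the Aitchison
    geometry of the simplex. Provides permutation inference, a distance
    correlation effect size, covariate adjustment by additive log-ratio
    residualization (Kennedy-Cade and Freedman-Lane permutation schemes) or
    by a stratified kernel, per-component follow-up rankings (leave-one-out
    distance correlation, optimized weighted Aitchison distance, log
    odds-ratio baseline), and an overdispersed multinomial-logit simulator
    for size, power and ranking-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
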