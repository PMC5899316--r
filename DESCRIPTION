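Package: flyssvep
Title: Steady-State Visually Evoked Potential Analysis for Drosophila
    Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of steady-state visually evoked
    potential (SSVEP) electroretinogram recordings from Drosophila, as
    used to phenotype visual gain control in Parkinson's disease models.
    Provides a synthetic ERG trial generator over an 8x8 temporal
    frequency by Michelson contrast stimulus sweep, coherent (complex)
    Fourier averaging with second-harmonic amplitude extraction,
    principal-component reduction of 64-condition response profiles with
    factorial ANOVA and Sidak-corrected simple effects, and a regularized
    linear discriminant classification suite with leave-one-out, Monte
    Carlo, N-way confusion-matrix, and bootstrap pairwise accuracy
    estimation, composed into a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
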