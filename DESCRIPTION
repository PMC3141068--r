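Package: mtldx
Title: Multivariate and Visual-Rating Discrimination of Medial Temporal
    Lobe Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare three ways of discriminating Alzheimer's
    disease from healthy ageing on structural MRI: orthogonal projections
    to latent structures discriminant analysis (OPLS-DA) of 57 regional
    cortical-thickness and volume measures, the Scheltens 0-4 visual
    rating of medial temporal lobe atrophy with age-dependent cutoffs,
    and manually outlined hippocampal volume.  Includes a from-scratch
    OPLS engine with seven-fold cross-validated Q2(Y), covariance
    loadings with jack-knifed confidence intervals, diagnostic-accuracy
    summaries (Wilson and log-method intervals for sensitivity,
    specificity, accuracy and likelihood ratios), transfer of trained
    AD-vs-control models to prediction of conversion from mild cognitive
    impairment, and a synthetic-cohort generator that emulates the
    statistical structure of such studies so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
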