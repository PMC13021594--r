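Package: posturo
Title: Time-Domain Posturographic Analysis of Force-Platform Stabilograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.invalid")
Description: Signal conditioning and time-domain feature extraction for
    center-of-pressure stabilograms recorded on static force platforms,
    aimed at sex- and age-related differences in postural control of older
    adults. Provides median and equiripple FIR low-pass filtering, transient
    trimming, six postural-control features (95% anteroposterior amplitude
    range, mass-normalized mean absolute moment, zero-crossing rates of sway
    and sway velocity, the stabilogram-diffusion critical time, and the
    steady-phase sample count), Romberg quotients, a seeded synthetic
    sway-cohort generator calibrated to per-group feature targets, and the
    cohort statistical layer: age stratification, sex balancing, alternating
    10-fold cross-validation, decision-tree sex classification, age
    prediction, rank-sum indicator tables and correlation matrices.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
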