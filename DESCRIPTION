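Package: octcvd
Title: Cardiovascular Risk Prediction from Retinal OCT via Latent
    Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting five-year
    myocardial-infarction/stroke risk from macular optical coherence
    tomography (OCT) volumes: scan quality indexing and lowest-fraction
    exclusion, event-window and comorbidity cohort rules with a
    STROBE-style ledger, 1:3 age/sex propensity matching, self-supervised
    variational-autoencoder (VAE) representation learning per eye with KL
    annealing, multimodal random-forest classification over seven
    data-channel combinations, and dual explainability: global Gini and
    modality importance plus a local latent-traversal vector-field method
    built on Lucas-Kanade optical flow. Because clinical OCT cohorts
    cannot be redistributed, a synthetic OCT phantom generator with a
    planted choroidal-morphology signal makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
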