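Package: mmrepair
Title: Detect and Repair Missing Modalities in Multimodal Wearable Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised learning for multimodal wearable sensor streams
    (IMU, ECG, EDA, respiration, temperature and similar signals) that remain
    usable when individual sensors drop out. Per-modality 1D convolutional
    encoders are trained with a hybrid objective of masked cross-modal
    reconstruction and NT-Xent contrastive alignment under simulated modality
    dropout; an attention fusion layer aggregates whichever modalities are
    available, a presence head detects which modalities are missing, and a
    conditioned decoder reconstructs the missing streams. Includes signal I/O
    and preprocessing (resampling, z-scoring, sliding windows), a synthetic
    multimodal data generator with a shared latent state, leave-one-subject-out
    evaluation with linear probes, dropout-robustness sweeps, and PCA/t-SNE
    latent-space exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
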