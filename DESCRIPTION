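Package: circrbp
Title: Self-Supervised Cross-View Learning for circRNA-RBP Binding Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding-protein (RBP) binding sites on circular RNA
    fragments with very few labels. Fixed-length sequence fragments are encoded
    under three complementary views (k-tuple nucleotide frequency patterns, a
    paragraph-vector k-mer embedding, and the electron-ion interaction
    pseudopotential with an optional position-specific trinucleotide propensity
    channel). A small pre-norm transformer with per-view convolutional input
    encoders is pretrained without labels on a cross-view sequence prediction
    task (each view's context vector must pick out the matching sample's
    per-position encoding of another view against in-batch negatives), then
    fine-tuned on a small labeled subset for binary site classification. Includes
    a seeded planted-motif synthetic data generator, ratio-sweep and ablation
    experiment runners, evaluation metrics, and tidy/ggplot2 result methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
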