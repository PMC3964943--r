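Package: motifshape
Title: DNA Shape Profiles and Shape-Augmented Binding Specificity Models
    for Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA structural features (minor groove width, propeller
    twist, roll and helix twist) for transcription factor binding sites by
    sliding-pentamer lookup against a structural query table, assembles
    aligned binding-site datasets from case-annotated FASTA and from protein
    binding microarray probes via PWM scanning with exact p-values, and
    analyses the resulting shape profiles: hierarchical clustering of
    per-sequence profiles, quantitative comparison of average profiles
    (Pearson correlation and Euclidean distance), per-position two-sample
    Kolmogorov-Smirnov differential tests, distance dendrograms across
    factors, and L2-regularized regression models of binding intensity that
    combine sequence and shape features, including a shuffled-shape control.
    A synthetic-data module generates pentamer tables, case-annotated FASTA
    and probe sets with planted motifs for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
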