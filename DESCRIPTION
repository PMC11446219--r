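Package: vbstools
Title: Social Dynamics Analytics for Group-Housed Mice in the Visible
    Burrow System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for continuous home-cage monitoring of
    group-housed mice in a visible burrow system (VBS) instrumented with
    an RFID reader grid and scored behavioral ethograms. Computes
    distance-traveled activity series and place-preference heatmaps from
    RFID streams; behavior occurrence tallies, pathological-aggression
    profiles and exact rank-sum genotype comparisons from ethogram
    events; per-day weighted directed social networks with node
    interaction strengths; per-interaction Glicko dominance ratings with
    emergence-of-dominance and despotism statistics; and a leave-one-out
    random-forest genotype discriminator with Gini-importance
    aggregation. A synthetic-data generator emulates both recording
    streams with genotype-dependent behavior rates, latent dominance
    structure and circadian activity modulation, so every stage is
    testable without access to animal recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
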