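Package: azresistome
Title: Airway Microbiome and Resistome Responses to Empiric Azithromycin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal upper-airway
    metatranscriptomic cohorts relating empiric azithromycin exposure to
    changes in the nasal microbiome and antimicrobial resistome. Provides
    negative-binomial background decontamination against batch-matched
    water controls, per-sample taxon and resistance-gene quality filters,
    reads-per-million and depth-per-million abundance transforms, alpha and
    beta diversity with principal-coordinate ordination and a one-factor
    permutational test, exposure-group and timepoint-window study designs
    with control matching, macrolide/lincosamide/streptogramin (MLS)
    resistome summaries, linear mixed-effects group comparisons,
    smooth-term longitudinal exposure models, rank-based pairwise tests,
    taxa-gene Spearman correlation networks, and a synthetic cohort
    generator with the statistical structure the pipeline assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils,
    withr,
    vegan,
    lme4,
    lmerTest,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
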