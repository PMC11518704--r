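Package: herbmet
Title: Metabolite Annotation, Sequential Metabolic Fate, and Bilinear-Attention
    Target Screening for Herbal LC-MS/MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain used in chemical profiling of
    multi-herb decoctions by high-resolution tandem mass spectrometry.
    Provides exact monoisotopic mass and adduct m/z arithmetic for molecular
    formulas, a declarative compound-class rulebase of diagnostic neutral
    losses and retro-Diels-Alder product ions, library-based spectrum
    annotation with identification-confidence tiers, assignment of sequential
    metabolic fate (gastric stability, intestinal/hepatic/systemic absorption,
    urinary and fecal excretion) from presence/absence tables, a bilinear
    attention drug-target interaction network (graph-convolutional drug
    encoder, convolutional protein encoder) trained with binary cross-entropy
    for ranking candidate bioactive metabolites against protein targets, and
    seeded synthetic-data generators with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
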