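Package: hydropep
Title: In Silico Analysis of Bioactive Peptides in Protein Hydrolysates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-side analysis of enzymatic protein
    hydrolysates characterised by peptide mass spectrometry. Computes and
    reconciles theoretical monoisotopic peptide masses against reported
    precursor masses (including single post-translational modification
    inference), scans hydrolysate peptides for encrypted bioactive motifs
    such as antihypertensive dipeptides, assesses sequence novelty against
    a local bioactive-peptide reference, and provides the assay arithmetic
    used in hydrolysate studies: percent ACE-1 inhibition, IC50 estimation
    from dose-response curves by four-parameter logistic fitting or
    log-linear interpolation, pH-stat degree of hydrolysis, recovery
    yields and nitrogen-to-protein conversion. Includes seeded simulators
    for enzymatic digestion, dose-response data and pH-stat titration
    traces so the full pipeline is testable without laboratory inputs.
    Ships a worked example: the peptide table of an Alcalase hydrolysate
    of the edible snail Helix aspersa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
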