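Package: icbcombo
Title: Combined Tumor Biomarkers for Checkpoint-Inhibition Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives four tumor biomarkers for immune checkpoint inhibition
    response -- neoepitope load (mutant peptides passing expression and
    MHC eluted-ligand percentile-rank filters), PD-L2 expression, cytolytic
    activity (geometric mean of GZMA and PRF1), and T-cell receptor
    diversity (Shannon entropy over CDR3 clone counts) -- from per-patient
    molecular tables, dichotomizes each at the cohort median, enumerates
    all biomarker combinations including at-least-k rules, and evaluates
    every combination against progression-free and overall survival with
    Kaplan-Meier curves, log-rank tests and two-group Cox hazard ratios.
    Includes a synthetic-cohort generator that emulates the latent
    immunogenicity structure of a small basket-trial cohort, down to the
    molecular input files, for end-to-end testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    withr,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
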