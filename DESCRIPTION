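Package: tierdx
Title: Diagnostic Yield and Cost-Effectiveness of Tiered Genetic Testing Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating stepwise ("dynamic") genetic diagnostic
    pathways in which an exome is sequenced once and reanalysed through
    successively wider virtual gene panels.  Computes marginal and cumulative
    diagnostic yields across testing tiers, compares paired binary outcomes
    with Cochran's Q and McNemar tests, models per-test reimbursement costs
    for alternative pathway strategies (panels-only, panels-then-exome,
    exome-first), and quantifies uncertainty of incremental cost and
    incremental diagnoses with a patient-level bootstrap rendered on the
    cost-effectiveness plane.  Ships a fully reconstructed 72-proband
    epilepsy/neurodevelopmental-disorder cohort as a worked fixture and a
    multinomial cohort simulator for synthetic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
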