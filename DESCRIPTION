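Package: wmscore
Title: RNA Modification Writer Expression Patterns and Prognostic Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers expression patterns of RNA modification "writer" enzymes
    (m6A, m1A, alternative polyadenylation and A-to-I editing machinery) in bulk
    tumour transcriptomes by resampling-based consensus clustering with PAC model
    selection, derives pattern-discriminating differentially expressed genes with
    an empirical-Bayes moderated t-test, condenses them into a per-patient
    principal-component score (WM_Score), dichotomizes the score at a
    survival-optimal cutpoint, and relates score groups to survival, tumour
    microenvironment enrichment (ssGSEA, GSVA-style and ESTIMATE-style scores),
    mutational burden and mutation co-occurrence. Ships a synthetic-cohort
    generator emulating the statistical structure of gastric-cancer expression
    cohorts so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    survival
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
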