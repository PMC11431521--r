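Package: gagdx
Title: Plasma GAGome and Cell-Free DNA Diagnostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating plasma glycosaminoglycan
    (GAGome) and cell-free DNA (cfDNA) diagnostic scores that discriminate
    lung cancer from benign lung disease. Implements the 17-disaccharide
    GAGome panel with compositional feature expansion (totals, charges,
    ratios, mass fractions) and a median-based detectability filter;
    Bayesian linear equivalence screening with region-of-practical-
    equivalence (ROPE) decisions and MCMC convergence gating; Bayesian
    logistic scoring models whose output is the log-odds of cancer;
    sensitivity-at-fixed-specificity evaluation with stratified bootstrap
    confidence intervals; a sequential combined cfDNA + GAGome test with a
    specificity budget; and a seeded synthetic cohort generator that
    emulates the statistical structure of the clinical study for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rjags,
    stats,
    tibble,
    tools,
    utils
Suggests:
    coda,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
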