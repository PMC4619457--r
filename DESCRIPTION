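Package: adrproxy
Title: Prescription-Pattern Proxies for ACE-Inhibitor Adverse Drug Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs treatment episodes from pharmacy dispensing records,
    classifies ACE-inhibitor starters into mutually exclusive prescription
    patterns (continuation, stop, switch to angiotensin receptor blockers or
    other antihypertensives), adjudicates coded primary-care events around the
    switch or stop date, and evaluates the patterns as proxies for
    ACE-inhibitor induced adverse drug reactions via positive and negative
    predictive values, sensitivity and specificity with Wilson score
    confidence intervals. Includes a synthetic longitudinal dispensing cohort
    generator with latent adverse-reaction ground truth, and closed-form
    expected predictive values for generator parameter sets, so the full
    pipeline is testable without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
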