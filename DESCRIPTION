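Package: roblab
Title: Risk-of-Bias Appraisal Engine for Clinical Laboratory Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An assessment engine for a pilot risk-of-bias instrument for
    clinical laboratory studies. Ships the instrument (three bias domains --
    collection and handling of samples, experimental methods, reporting of
    the results -- with fourteen signalling questions answered
    yes/no/no-information at the outcome level) as machine-readable package
    data, validates per-study per-outcome assessment records, aggregates
    answers into domain and overall risk-of-bias judgements with the
    count-based rule, quantifies dual-assessor agreement with Cohen's kappa,
    renders traffic-light summaries, and simulates synthetic assessment sets
    for testing and calibration. A command-line interface covers the
    systematic-reviewer workflow from blank templates to narrative reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
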