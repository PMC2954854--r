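Package: regretdca
Title: Regret-Based Decision Curve Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decision curve analysis reformulated in terms of
    anticipated regret. Elicits a decision maker's treatment threshold
    probability from dual visual-analog-scale ratings of the regret of
    omission (withholding needed treatment) and commission (giving
    unnecessary treatment), computes expected regret and net expected
    regret difference (NERD) curves for the treat-all, treat-none and
    prediction-model strategies over a cohort of predicted risks and
    observed outcomes, and applies acceptable-regret logic to recommend
    the strategy whose potential for regret the decision maker can
    tolerate. Includes a synthetic-cohort simulator with controllable
    prevalence, discrimination and calibration for testing model
    evaluation workflows end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
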