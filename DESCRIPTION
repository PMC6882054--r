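Package: endorsim
Title: Simulating True and False Positive Rates of Trial Endorsement Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monte-Carlo machinery for comparing statistical criteria used to
    endorse a treatment after a series of two-arm clinical trials: counting
    statistically significant one-sided t-tests (the classical two-pivotal-trials
    rule), lower bounds of fixed-effect, DerSimonian-Laird and
    Hartung-Knapp-Sidik-Jonkman meta-analytic 95% confidence intervals, and
    one-sided Jeffreys-Zellner-Siow Bayes factors computed on the pooled data,
    together with minimum Bayes factors calibrated from p-values. Includes a
    synthetic trial generator with mixture-of-null effect distributions and
    fixed- or random-effects heterogeneity, decision classification against
    clinically meaningful effect thresholds, true/false positive rate
    aggregation, and confidence interval coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2
Config/testthat/edition: 3
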