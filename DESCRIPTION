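Package: lipidmrm
Title: Scheduled Multiple Reaction Monitoring Toolkit for Targeted Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating high-throughput scheduled
    multiple reaction monitoring (MRM) lipidomics assays. Builds lipid-class
    aware MRM transition libraries from molecular-formula first principles
    (including sn-position triacylglycerol isomer transitions and phospholipid
    fatty-acyl transitions), assigns variable retention-time windows and
    relative dwell-time weights under a fixed instrument cycle-time budget,
    simulates LC-MRM acquisition with Poisson shot noise to compare
    unscheduled, fixed-window and variable-window scheduling, and provides
    method-validation statistics (limits of blank/detection/quantitation,
    linearity, spike recovery, coefficient of variation) together with a
    two-group differential screening pipeline (class-sum normalization,
    empirical-Bayes batch adjustment, Wilcoxon rank-sum screening,
    Benjamini-Hochberg adjustment and shadow-feature random-forest selection).
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
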