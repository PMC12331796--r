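Package: tachometric
Title: Tachometric Analysis of Urgent Visuomotor Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for urgent-decision (deadline) paradigms such as
    the urgent Eriksen flanker task: computes raw processing times (rPT = RT -
    gap - SOA), filters trials to the analysis window, bins accuracy on a 1-ms
    grid, smooths the tachometric function by local polynomial regression,
    extracts below-chance dip statistics with permutation and bootstrap
    inference, draws binomial confidence bands around chance, and computes
    one-sided binomial-proportion Bayes factors per rPT bin. Includes a
    synthetic-data generator that reproduces balanced gap/congruency/SOA
    designs and a parametric observer model, so the full pipeline is testable
    end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    withr
Config/testthat/edition: 3
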