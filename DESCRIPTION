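Package: operantiiv
Title: Intra-Individual Variability Analysis of Operant Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intra-individual variability (IIV) in
    operant-conditioning experiments. Converts time-stamped
    operant-chamber event streams (lever presses, door openings,
    reinforcers) into per-segment counts of three behavioral traits
    (hyperactivity, impulsiveness, inattention), computes individual
    phenotypic dispersion (the mean absolute deviation of per-segment
    behavior from the session mean, one value per subject per session
    per trait), and compares dispersion between groups with
    Kruskal-Wallis ranking, linear models on log-transformed
    dispersion with variance proportions, and repeated-measures trend
    analyses among and within sessions. Includes a seeded synthetic
    event-stream generator emulating a two-strain (SHR vs WKY)
    variable-interval operant study so the whole pipeline is testable
    without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
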