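Package: focalsna
Title: Post-Conflict Proximity Networks from Focal-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed, observation-time-normalized proximity networks
    from focal-sampling behavioral event logs of group-housed primates,
    stratified by post-conflict context (neutral, post-outburst,
    post-intragroup, post-intergroup). Computes eigenvector centrality and
    in-/out-/total node strength per network, and runs the accompanying
    statistical battery: Lilliefors normality screening with Monte Carlo
    p-values, rank-transform one-way ANOVA with a priori orthogonal contrasts,
    two-way rank ANOVA with Type III sums of squares, Spearman validation of
    behavior pooling, and a replicated goodness-of-fit G-test with
    observation-time expectations. Includes a stochastic generator of focal
    schedules, disruption events, and dyadic interaction bouts for power and
    type-I-error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    car,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
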