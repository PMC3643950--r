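Package: intentnet
Title: Behavioral Intention as Parallel Constraint Satisfaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A constraint-satisfaction neural-network account of the Theory of
    Reasoned Action. Behavioral intention is read out from a paired-valence
    auto-associator whose settling dynamics reconcile learned internal
    constraints (connection strengths trained from past social contexts) with
    clamped external constraints (others' beliefs in the immediate context).
    The package provides the network (topology, synchronous settling,
    activation carry-over), batch training by the generalized delta rule with
    error evaluated on late settling cycles, generators for probabilistic and
    synthetic belief-survey input sets, the factorial simulation designs, and
    the intention-scoring analysis: categorical cross-tabulation with exact
    (Freeman-Halton) contingency-table inference, per-category summaries, and
    dummy-coded regression of the continuous intention score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
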