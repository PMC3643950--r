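---
title: "Behavioral intention as parallel constraint satisfaction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral intention as parallel constraint satisfaction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentnet)
```

## The model

The Theory of Reasoned Action (TRA) treats behavioral intention as the product
of attitudes and perceived norms, which are themselves formed from beliefs.
`intentnet` implements a dynamic re-conceptualization of that chain: intention
is a *state* of a recurrent constraint-satisfaction network over beliefs, not a
weighted sum. Fourteen beliefs about a health behavior (nine outcome beliefs,
five normative beliefs) are each split between two visible processing units:
one carries the belief's positive valence (the *intend* bank), the other its
negative valence (the *not-intend* bank).

Three kinds of constraint act on these units:

* **Internal processing constraints** — learned connection strengths among the
  units. Within each valence bank the belief units are fully interconnected;
  two banks of ten hidden units (one attached to each visible bank) let the
  network carry higher-order structure. These weights encode the statistics of
  past social contexts and are produced by `train_weights()`.
* **A fixed inter-valence constraint** — the two units of the same belief
  inhibit each other with a frozen weight of −0.20 in both directions. No
  other visible connections cross the banks.
* **External processing constraints** — an input pattern representing the
  beliefs of others in the immediate social context: a binary vector over the
  intend bank and its bitwise complement over the not-intend bank. Each bit
  enters the net input of its unit additively, scaled by the *clamp strength*
  (soft clamping). Clamp strength models the weight a person gives to others'
  beliefs; the study design uses 0.10 (weak) and 0.50 (strong).

Given an input, the network *settles*: all units are updated synchronously for
nine cycles, each unit passing its net input (recurrent input + bias +
clamped external term) through a logistic squashing function restricted to
(0, 1). The state on the ninth cycle is read out. Between consecutive input
patterns a small portion of activation carries over:
`init = rest + kappa * (final - rest)` with `kappa = 0.1` and `rest = 0.5` by
default; the carry-over chain resets between runs, a run being the analog of
one person.

Intention is read off the settled state as the mean intend-bank activation
minus the mean not-intend-bank activation — a continuous score in (−1, 1),
binned into four categories, (−1, −0.5] = 1 (NO!), (−0.5, 0] = 2 (no),
(0, 0.5] = 3 (yes), (0.5, 1) = 4 (YES!), to align with a four-level survey
intention item.

## Learning

`train_weights()` generates the internal constraints by the generalized delta
rule in batch mode for 200 epochs. The network is an auto-associator: the
target for each input pattern is the 28-bit pattern itself, and the error is
evaluated on the visible units only, over settling cycles 7–9, with the clamp
fixed at 0.50. Gradients are computed by backpropagation through the unrolled
nine-cycle settling, *including* through the carry-over link between
consecutive patterns, so the batch gradient is exact for the whole
presentation chain (the test suite verifies every trainable weight against
central finite differences to a relative tolerance of 1e-4). The fixed
inter-valence links and the structural zeros receive no updates by
construction.

## Choices where the design was open

Several ingredients of the model are underdetermined, and the package had to
fix them. Each is exposed as a configurable argument; the defaults below are
the package's study conditions.

* **The "modified" logistic.** The activation function is described only as a
  modified logistic restricted to (0, 1). We implement
  `f(net) = plogis(gain * net)` clipped to `[1e-6, 1 - 1e-6]`, with
  **gain = 10** as the default. The gain is the substantive part of the
  interpretation: with additive soft clamping, a clamped-on bit contributes
  only +0.5 to a unit's net input, and at unit gain that shift moves a
  logistic unit by at most ~0.12 — far too weak for the settling dynamics to
  binarize, so batch training collapses to a base-rate (bias-only) solution
  with almost no input sensitivity, contradicting the model's central
  qualitative behavior (strong clamping should let the external context
  dominate). At gain 10 a clamped bit is nearly decisive for its unit, the
  fixed −0.20 pair inhibition acts as an effective winner-take-all within
  each belief, and the trained network reproduces the expected pattern:
  under strong clamping the bank means track the external context's
  positive-valence rate, while under weak clamping the learned internal bias
  dominates. The gain was selected by sweeping 1–12 and judging only
  (a) monotone convergence of the batch training error within the stated 200
  epochs and (b) those qualitative clamping signatures.
* **Learning rate and momentum.** Neither is stated. The default is
  `learning_rate = 2e-4` with `momentum = 0` and sum-squared error: at gain
  10 this step gives monotone batch convergence over 200 epochs on a
  50-pattern training set (error 792 → 3.7 in the packaged configuration),
  whereas substantially larger steps oscillate or diverge. Momentum and a
  cross-entropy error measure are available but off by default.
* **Carry-over magnitude.** "A small portion" is implemented as
  `kappa = 0.1`, applied across successive patterns within a run (and within
  a training batch), resetting between runs. The first pattern of a run
  starts from a uniform resting state of 0.5, the logistic of zero net input.
* **Clamping.** External input enters additively in the net input
  (`clamp * bit`), per the description of clamp strength as the connection
  weight from each external input; activations are never hard-clamped.
* **Weight tying and initialization.** The bidirectional visible–hidden
  connections are two independent directed weights (no tying is stated).
  Trainable weights initialize i.i.d. uniform on [−0.1, 0.1] with a recorded
  seed; biases start at zero and are trained as weights from a constant-on
  unit.
* **Presentation order.** Within a run, the same 50 patterns are presented in
  a fixed order across the 10 epochs (re-ordering across epochs is not
  stated).

## Input sets and the synthetic survey generator

Two families of input sets drive the simulations:

* `bernoulli_patterns()` draws each belief's positive bit i.i.d.
  Bernoulli(p) — the P25 / P50 / P75 sets (p = 0.25, 0.50, 0.75) represent
  contexts leaning against, neutral to, and towards the behavior.
* `synth_survey()` + `surveys_to_patterns()` emulate the belief-survey data
  the empirical input sets came from: 14 integer responses on a −8..8 scale
  with a zero midpoint, transformed to bits by sign (negative → 0, positive →
  1, zero → Bernoulli(0.5)), complemented into the not-intend half. Valence
  is preserved; magnitude is discarded by the transform.

The original adolescent survey (three female sub-populations: 10th-grade
virgins, N = 105; 12th-grade virgins, N = 66; 12th-grade non-virgins, N = 73)
is not public, so the generator is calibrated to the published aggregate
structure: mean positive-valence fractions of the transformed input sets of
0.29 (F10V), 0.36 (F12V) and 0.42 (F12NV). Per-belief positivity is
deliberately heterogeneous — hedonic/affiliative outcome beliefs lean
positive, health-risk outcomes and most normative referents lean negative —
and the profile is scaled so the expected transformed positivity hits the
group target exactly, accounting for the zero-response probability (0.1 by
default, a free parameter the source does not constrain). Magnitudes are
uniform on 1..8. A four-level intention item is drawn from a
cumulative-logit link on each respondent's realized mean positivity,
`P(Y <= k) = plogis(alpha_k - 6 m)`, with thresholds (1.66, 3.26, 6.34)
placed so that at mean positivity 0.29 the expected category margin echoes
the published 50/36/18/1 distribution over NO!/no/yes/YES!.

What the generator does *not* emulate: real item-level covariance beyond the
heterogeneous base rates (empirical beliefs are correlated within
respondents in ways Bernoulli sampling cannot reproduce), item nonresponse,
survey weights, and the longitudinal design. Consequently the simulation
tests show that the *mechanism* behaves as published under matched aggregate
conditions — they do not reproduce the respondent-level numbers (the
published M = −0.413, adjusted R² = 0.28 and F(3, 101) = 14.39 of the
Simulation III analysis are tied to the original data and are replaced here
by direction and range properties).

## The simulation designs

* **Simulations I and II** (`run_condition()`): factorial input-set × clamp
  designs; 30 runs per condition, each run 10 epochs of the same 50 patterns
  (500 exposures), recording the 9th-cycle state per exposure, learning off.
  Probabilistic conditions regenerate a fresh random 50-pattern set per run;
  survey-derived conditions sample 50 patterns without replacement from
  their input set per run. `bank_summary()` reports each bank's mean over
  all exposures and the SD across per-run means with n (not n−1) in the
  denominator, the population form used for the published error bars.
* **Simulation III** (`run_single_pass()`): the survey-trained network is
  shown each of the 105 respondents' patterns exactly once under strong
  clamping; each settled state is scored and categorized, cross-tabulated
  against the generated empirical intention item, and analysed by the exact
  test, per-category means (`group_stats()`), and a dummy-coded OLS
  regression (`dummy_regression()`, reference category 1), whose
  coefficients equal group-mean contrasts by the one-way ANOVA identity.

The packaged test suite runs these designs with 10 runs per condition rather
than 30 — the bank means it asserts on average 5,000 exposures per
condition, where the run-level SD of the trained network is of order 0.003,
so the scaled-down means sit well inside the ±0.10 assertion bands (a test
verifies that 5-run and 30-run condition means agree within 0.02).

## Exact contingency-table inference

For a table of counts with both margins fixed, the conditional probability of
the table is multivariate hypergeometric,
`prod(rowtot!) prod(coltot!) / (N! prod(cell!))`, accumulated in log-space
(`exact_point_probability()`). The Freeman–Halton two-sided test
(`freeman_halton_p()`) sums this mass over every margin-consistent table
whose point probability does not exceed the observed table's, with a 1e-7
relative tie tolerance; tables are enumerated row-wise with per-cell lower
and upper bounds so the recursion visits no dead branches, and an enumeration
guard (2e6 tables) redirects oversized problems to a Monte-Carlo mode that
samples margin-fixed tables by Patefield's algorithm (`stats::r2dtable`).
On the packaged reference cross-tabulation (N = 105), the tail sum is
0.0004355 — the value the published analysis reports for this table under
"Fisher's Exact Test". The phrase "the probability of sampling this
cross-tabulation, given the marginals" could also be read as the point
probability of the table itself; that quantity is 3.38e-6 for the same
table, which is why the package computes and reports both, side by side, with
the tail sum as the headline value.

Degenerate inputs are handled explicitly: a table with a single nonzero row
(or column) is forced by its margins and has probability 1; empty rows or
columns are dropped before Monte-Carlo sampling since their cells are
structurally zero.

## Numerical choices

* Activations are clipped to `[1e-6, 1 - 1e-6]`; the logistic derivative
  `gain * a * (1 - a)` is used everywhere (at the clip boundary it is of
  order 1e-5, which is immaterial at the weight scales the package trains).
* Intention scores of exactly 0 fall in category 2 and scores of exactly
  −0.5 in category 1, per the half-open cut-points; +1 is unreachable with
  activations strictly inside (0, 1).
* All table probabilities use `lgamma` accumulation; the tail sum is
  accumulated by log-add-exp.
* Standard errors in `group_stats()` use the sample SD (n−1) over sqrt(n)
  and are reported as missing for singleton categories.

## Limitations

* The gain interpretation of the "modified" logistic is a reconstruction;
  other modifications (offset, temperature schedule) would change the
  quantitative bank means, though the qualitative clamping dissociation was
  robust across gains 8–12 in our sweeps.
* The synthetic survey generator matches aggregate valence structure, not
  respondent-level covariance; analyses that depend on the joint belief
  distribution (e.g. the exact size of the model–empirical intention
  association) are weaker under the generator than in the published data.
* Asynchronous or stochastic updating, continuous-valued external inputs,
  and the classic expectancy-value aggregation are out of scope.
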