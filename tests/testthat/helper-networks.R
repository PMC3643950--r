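# Shared fixtures, built once per test run and cached.
# The trained networks use the package's study defaults: 14 beliefs, 10 hidden
# units per bank, 200 batch epochs, clamp 0.5 during training.

.fixtures <- new.env(parent = emptyenv())

small_topology <- function() make_topology(3, 2)

small_weights <- function(seed = 7, scale = 0.1) {
  init_weights(small_topology(), seed = seed, scale = scale)
}

# P25-trained weight set: internal constraints learned from contexts leaning
# against intending (positive-valence probability 0.25).
trained_p25 <- function() {
  if (is.null(.fixtures$p25)) {
    w0 <- init_weights(make_topology(14, 10), seed = 11, scale = 0.1)
    pats <- pattern_matrix(bernoulli_patterns(50, p = 0.25, seed = 12))
    .fixtures$p25 <- train_weights(w0, pats)
  }
  .fixtures$p25
}

# Synthetic belief survey emulating the F10V group (n = 105, mean transformed
# positivity 0.29), with its transformed pattern set and a weight set trained
# on those patterns.
f10v_survey <- function() synth_survey(105, survey_spec("F10V"), seed = 201)

trained_f10v <- function() {
  if (is.null(.fixtures$f10v)) {
    survey <- f10v_survey()
    patterns <- surveys_to_patterns(survey, seed = 202)
    w0 <- init_weights(make_topology(14, 10), seed = 11, scale = 0.1)
    .fixtures$f10v <- list(
      survey = survey,
      patterns = patterns,
      fit = train_weights(w0, pattern_matrix(patterns))
    )
  }
  .fixtures$f10v
}

# Bank-swap permutation: intend <-> not-intend, hidden A <-> hidden B.
bank_swap_permutation <- function(topology) {
  c(topology$notintend, topology$intend, topology$hidden_b, topology$hidden_a)
}
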