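#' Probabilistic input-pattern sets
#'
#' Generates binary input patterns for the network. Each pattern is a vector
#' of `n_beliefs` positive-valence bits drawn i.i.d. Bernoulli(`p`), followed
#' by its bitwise complement (the not-intend bank bits). `p = 0.25`, `0.50`
#' and `0.75` give the P25, P50 and P75 sets: contexts leaning against,
#' neutral to, and towards intending the behavior.
#'
#' @param n_patterns Number of patterns to generate.
#' @param p Probability that the positive valence of each belief is on.
#' @param seed Integer seed (reproducible).
#' @param n_beliefs Number of beliefs (default 14).
#' @return A tibble of class `intent_patterns` with one row per pattern and
#'   columns `pos_1..pos_n` then `neg_1..neg_n`; the provenance label is
#'   stored in the `"label"` attribute.
#' @examples
#' bernoulli_patterns(5, p = 0.25, seed = 1)
#' @export
bernoulli_patterns <- function(n_patterns, p, seed = 1L, n_beliefs = 14) {
  if (p < 0 || p > 1) stop("`p` must be in [0, 1].", call. = FALSE)
  set.seed(as.integer(seed))
  pos <- matrix(as.integer(stats::runif(n_patterns * n_beliefs) < p),
                nrow = n_patterns)
  as_intent_patterns(pos, label = sprintf("P%02.0f", 100 * p))
}

# Internal: wrap a positive-bit matrix (rows = patterns) into the pattern
# tibble, appending the complement bits.
as_intent_patterns <- function(pos, label = NA_character_) {
  nb <- ncol(pos)
  full <- cbind(pos, 1L - pos)
  colnames(full) <- c(paste0("pos_", seq_len(nb)), paste0("neg_", seq_len(nb)))
  out <- tibble::as_tibble(as.data.frame(full))
  attr(out, "label") <- label
  class(out) <- c("intent_patterns", class(out))
  out
}

#' Extract the binary pattern matrix from a pattern tibble
#'
#' @param patterns A tibble from [bernoulli_patterns()], [surveys_to_patterns()]
#'   or [sample_run_patterns()] (any data frame whose `pos_*`/`neg_*` columns
#'   hold the bits).
#' @return Integer matrix, one row per pattern, `2 * n_beliefs` columns.
#' @export
pattern_matrix <- function(patterns) {
  cols <- grep("^(pos|neg)_", names(patterns), value = TRUE)
  m <- as.matrix(patterns[cols])
  storage.mode(m) <- "integer"
  m
}

#' Transform survey responses into input patterns
#'
#' Maps each belief measured on the integer -8..8 scale onto the binary
#' valence structure of the network: negative values become 0, positive values
#' 1, and zeros are resolved probabilistically (probability 0.5 of assigning
#' 1). The not-intend bank bits are the logical complement of the intend bank
#' bits. Valence is preserved; magnitude is discarded.
#'
#' @param survey A data frame with belief columns `belief_1..belief_n`
#'   (integers in -8..8), e.g. from [synth_survey()].
#' @param seed Seed for the probabilistic resolution of zero responses.
#' @return A tibble of patterns, one row per respondent (see
#'   [bernoulli_patterns()] for the layout); rows stay aligned with `survey`.
#' @export
surveys_to_patterns <- function(survey, seed = 1L) {
  bcols <- grep("^belief_", names(survey), value = TRUE)
  if (length(bcols) == 0) {
    stop("`survey` must contain `belief_*` columns.", call. = FALSE)
  }
  vals <- as.matrix(survey[bcols])
  if (any(vals != round(vals)) || any(abs(vals) > 8)) {
    stop("Belief values must be integers in [-8, 8].", call. = FALSE)
  }
  set.seed(as.integer(seed))
  pos <- matrix(0L, nrow(vals), ncol(vals))
  pos[vals > 0] <- 1L
  nz <- vals == 0
  pos[nz] <- as.integer(stats::runif(sum(nz)) < 0.5)
  as_intent_patterns(pos, label = attr(survey, "label") %||% "survey")
}

#' Specification of the synthetic belief-survey generator
#'
#' Builds a generator specification emulating the structure of an adolescent
#' belief survey: 14 beliefs (nine outcome, five normative) on an integer
#' -8..8 scale with a zero midpoint, plus a 4-level intention item. Per-belief
#' positivity is heterogeneous (some beliefs commonly endorsed positively,
#' others rarely), scaled so that the expected positive-valence fraction of
#' the *transformed* patterns (zeros resolved at probability 0.5) matches
#' `mean_positivity`. The named groups carry the target mean positivities of
#' the three female sub-populations the model is analysed with: 10th-grade
#' virgins (0.29), 12th-grade virgins (0.36) and 12th-grade non-virgins
#' (0.42).
#'
#' The intention item is linked to each respondent's realized mean belief
#' positivity through a cumulative-logit map, `P(Y <= k) =
#' plogis(alpha_k - slope * m)`; the default thresholds are calibrated so that
#' at mean positivity 0.29 the expected category frequencies echo the
#' published 50/36/18/1 margin over NO!/no/yes/YES!.
#'
#' @param group `"F10V"`, `"F12V"` or `"F12NV"`, or `NULL` to give
#'   `mean_positivity` directly.
#' @param mean_positivity Target expected positive-valence fraction of the
#'   transformed patterns.
#' @param zero_prob Probability that a belief response is exactly 0.
#' @param shape Length-14 non-negative relative-positivity profile (mean 1);
#'   scaled to hit the target.
#' @param intention_slope Slope of the cumulative-logit intention link.
#' @param intention_alpha Three increasing cumulative-logit thresholds.
#' @return A list of class `survey_spec`.
#' @export
survey_spec <- function(group = NULL, mean_positivity = NULL, zero_prob = 0.1,
                        shape = NULL, intention_slope = 6,
                        intention_alpha = c(1.66, 3.26, 6.34)) {
  targets <- c(F10V = 0.29, F12V = 0.36, F12NV = 0.42)
  if (!is.null(group)) {
    group <- match.arg(group, names(targets))
    mean_positivity <- unname(targets[group])
  } else if (is.null(mean_positivity)) {
    stop("Give either `group` or `mean_positivity`.", call. = FALSE)
  }
  if (is.null(shape)) {
    # outcome beliefs 1-9 (feel good, popular, loved, experienced, STD,
    # pregnancy, regret, HIV, stress), normative 10-14; hedonic/affiliative
    # outcomes lean positive, health-risk outcomes and most referents negative
    shape <- c(2.2, 1.2, 2.0, 2.2, 0.25, 0.30, 0.60, 0.20, 0.50,
               0.50, 1.6, 1.2, 0.90, 0.35)
  }
  if (any(shape < 0)) stop("`shape` must be non-negative.", call. = FALSE)
  shape <- shape / mean(shape)
  # expected transformed positivity = (1 - z) * mean(p) + z / 2
  target_p <- (mean_positivity - zero_prob / 2) / (1 - zero_prob)
  if (target_p < 0 || target_p > 1) {
    stop("`mean_positivity` is unreachable at this `zero_prob`.", call. = FALSE)
  }
  positivity <- target_p * shape
  if (any(positivity > 1)) {
    stop("Scaled per-belief positivity exceeds 1; flatten `shape`.",
         call. = FALSE)
  }
  structure(
    list(group = group %||% sprintf("P%02.0f", 100 * mean_positivity),
         mean_positivity = mean_positivity, positivity = positivity,
         zero_prob = zero_prob, intention_slope = intention_slope,
         intention_alpha = intention_alpha),
    class = "survey_spec"
  )
}

#' Generate a synthetic belief survey
#'
#' Draws respondent-level belief vectors from a [survey_spec()]: each belief
#' is 0 with probability `zero_prob`, otherwise its sign is positive with the
#' belief's positivity probability, and its magnitude is uniform on 1..8. The
#' 4-level intention item is drawn from the cumulative-logit link given the
#' respondent's realized mean positivity (fraction of positive beliefs plus
#' half the fraction of zeros, i.e. the expected positive-bit fraction after
#' the valence transform).
#'
#' @param n_respondents Number of respondents.
#' @param spec A `survey_spec` (or a group name passed to [survey_spec()]).
#' @param seed Integer seed.
#' @return A tibble with columns `respondent`, `belief_1..belief_14`,
#'   `intention`; the spec's group label is stored in the `"label"` attribute.
#' @examples
#' synth_survey(5, survey_spec("F10V"), seed = 1)
#' @export
synth_survey <- function(n_respondents, spec = survey_spec("F10V"), seed = 1L) {
  if (is.character(spec)) spec <- survey_spec(spec)
  stopifnot(inherits(spec, "survey_spec"))
  nb <- length(spec$positivity)
  set.seed(as.integer(seed))
  is_zero <- matrix(stats::runif(n_respondents * nb) < spec$zero_prob,
                    nrow = n_respondents)
  is_pos <- matrix(stats::runif(n_respondents * nb), nrow = n_respondents) <
    matrix(spec$positivity, n_respondents, nb, byrow = TRUE)
  mag <- matrix(sample.int(8, n_respondents * nb, replace = TRUE),
                nrow = n_respondents)
  beliefs <- ifelse(is_zero, 0L, ifelse(is_pos, mag, -mag))

  m <- rowMeans(beliefs > 0) + 0.5 * rowMeans(beliefs == 0)
  cum <- stats::plogis(outer(-spec$intention_slope * m, spec$intention_alpha, "+"))
  u <- stats::runif(n_respondents)
  intention <- 1L + rowSums(u > cum)

  colnames(beliefs) <- paste0("belief_", seq_len(nb))
  out <- tibble::tibble(respondent = seq_len(n_respondents)) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(beliefs))) |>
    dplyr::mutate(intention = as.integer(intention))
  attr(out, "label") <- paste0("synthetic-", spec$group)
  out
}

#' Sample run patterns without replacement
#'
#' Draws `n` distinct patterns from a pattern set in randomized order — the
#' sampling scheme used to build each run's presentation list from an
#' empirical-style input set.
#'
#' @param patterns A pattern tibble.
#' @param n Number of patterns to draw (at most `nrow(patterns)`).
#' @param seed Integer seed.
#' @return A pattern tibble of `n` rows.
#' @export
sample_run_patterns <- function(patterns, n, seed = 1L) {
  if (n > nrow(patterns)) {
    stop("Cannot sample ", n, " patterns without replacement from ",
         nrow(patterns), ".", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- patterns[sample.int(nrow(patterns), n), , drop = FALSE]
  attr(out, "label") <- attr(patterns, "label")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
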