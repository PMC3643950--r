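#' Run one simulation condition
#'
#' Executes the factorial-design workhorse: `n_runs` independent runs (a run
#' is analogous to an individual person), each consisting of `n_epochs_per_run`
#' epochs of the same `n_patterns_per_run` input patterns in fixed order.
#' Activation carried over between consecutive pattern presentations is
#' chained across the whole run and reset between runs; learning is off.
#' The state at the recorded settling cycle (default the 9th and last) is
#' summarized per exposure as the mean activation of each visible valence
#' bank.
#'
#' Pattern provenance follows the condition type: pass a *pattern tibble* to
#' sample `n_patterns_per_run` patterns without replacement per run
#' (empirical-style sets), or a *generator function* `function(n, seed)`
#' returning a pattern tibble to draw a fresh random set per run
#' (probabilistic P25/P50/P75-style conditions; see [p_set_generator()]).
#'
#' @param weights Trained `intent_weights`.
#' @param patterns Pattern tibble or generator `function(n, seed)`.
#' @param clamp Clamp strength (the study-design levels are 0.10 and 0.50).
#' @param n_runs Number of runs (default 30).
#' @param n_epochs_per_run Epochs of the pattern list per run (default 10).
#' @param n_patterns_per_run Patterns per run (default 50).
#' @param n_cycles Settling cycles per pattern; the recorded cycle is the last.
#' @param kappa Carry-over proportion between consecutive patterns.
#' @param seed Master seed; per-run seeds are derived reproducibly.
#' @param rest,gain,eps Settling parameters, as in [settle()].
#' @param condition Optional condition label recorded in the output (defaults
#'   to the pattern set's label).
#' @return A tibble of class `intent_runs` with one row per exposure:
#'   `condition`, `clamp`, `run`, `epoch`, `pattern`, `intend_mean`,
#'   `notintend_mean`.
#' @export
run_condition <- function(weights, patterns, clamp, n_runs = 30,
                          n_epochs_per_run = 10, n_patterns_per_run = 50,
                          n_cycles = 9, kappa = 0.1, seed = 1L, rest = 0.5,
                          gain = 10, eps = 1e-6, condition = NULL) {
  stopifnot(inherits(weights, "intent_weights"))
  topo <- weights$topology
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  if (is.null(condition)) {
    condition <- if (is.function(patterns)) "generated" else
      attr(patterns, "label") %||% "patterns"
  }
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_pats <- if (is.function(patterns)) {
      patterns(n_patterns_per_run, run_seeds[r])
    } else {
      sample_run_patterns(patterns, n_patterns_per_run, seed = run_seeds[r])
    }
    pm <- pattern_matrix(run_pats)
    if (!is.null(attr(run_pats, "label")) && condition == "generated") {
      condition <- attr(run_pats, "label")
    }
    n_expo <- n_epochs_per_run * n_patterns_per_run
    im <- numeric(n_expo)
    nm <- numeric(n_expo)
    prev_final <- NULL
    e <- 0L
    for (ep in seq_len(n_epochs_per_run)) {
      for (k in seq_len(n_patterns_per_run)) {
        e <- e + 1L
        init <- carryover_state(prev_final, kappa = kappa, rest = rest,
                                n_units = topo$n_units)
        traj <- settle(weights, pm[k, ], clamp, n_cycles = n_cycles,
                       init = init, rest = rest, gain = gain, eps = eps)
        final <- traj[n_cycles, ]
        im[e] <- mean(final[topo$intend])
        nm[e] <- mean(final[topo$notintend])
        prev_final <- final
      }
    }
    out[[r]] <- tibble::tibble(
      condition = condition, clamp = clamp, run = r,
      epoch = rep(seq_len(n_epochs_per_run), each = n_patterns_per_run),
      pattern = rep(seq_len(n_patterns_per_run), n_epochs_per_run),
      intend_mean = im, notintend_mean = nm
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("intent_runs", class(res))
  res
}

#' Generator for probabilistic input conditions
#'
#' Returns a `function(n, seed)` producing a fresh Bernoulli(`p`) pattern set,
#' the per-run regeneration scheme of the probabilistic conditions.
#'
#' @param p Positive-valence probability.
#' @param n_beliefs Number of beliefs.
#' @return A generator function for [run_condition()].
#' @export
p_set_generator <- function(p, n_beliefs = 14) {
  force(p); force(n_beliefs)
  function(n, seed) bernoulli_patterns(n, p = p, seed = seed,
                                       n_beliefs = n_beliefs)
}

#' Summarize valence-bank activation over a condition
#'
#' Collapses exposure-level records to the per-bank mean activation across all
#' exposures and runs, with the standard deviation computed across the per-run
#' means using n (the number of runs) in the denominator — the population form
#' used for the error bars of the simulation figures.
#'
#' @param records An `intent_runs` tibble from [run_condition()] (conditions
#'   may be concatenated with [dplyr::bind_rows()]).
#' @return A tibble of class `bank_summary`: one row per condition x clamp x
#'   bank with `mean`, `sd_runs`, `n_runs`, `n_exposures`.
#' @export
bank_summary <- function(records) {
  long <- tidyr::pivot_longer(records, c("intend_mean", "notintend_mean"),
                              names_to = "bank", values_to = "activation")
  long$bank <- ifelse(long$bank == "intend_mean", "intend", "not_intend")
  out <- long |>
    dplyr::group_by(.data$condition, .data$clamp, .data$bank, .data$run) |>
    dplyr::summarise(run_mean = mean(.data$activation),
                     n_expo = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$condition, .data$clamp, .data$bank) |>
    dplyr::summarise(
      mean = mean(.data$run_mean),
      sd_runs = sqrt(mean((.data$run_mean - mean(.data$run_mean))^2)),
      n_runs = dplyr::n(),
      n_exposures = sum(.data$n_expo),
      .groups = "drop"
    )
  class(out) <- c("bank_summary", class(out))
  out
}

#' Plot bank-activation summaries
#'
#' Reproduces the layout of the simulation figures: mean activation of each
#' valence bank per input condition, with error bars of one run-level standard
#' deviation, faceted by clamp strength.
#'
#' @param object A `bank_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bank_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$mean,
                               colour = .data$bank, group = .data$bank)) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.5, 0.75), linetype = "dashed",
                        colour = "darkgreen", linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd_runs,
                                        ymax = .data$mean + .data$sd_runs),
                           width = 0.15) +
    ggplot2::scale_colour_manual(values = c(intend = "firebrick",
                                            not_intend = "grey40")) +
    ggplot2::facet_wrap(~clamp, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Input condition", y = "Mean bank activation",
                  colour = "Valence bank") +
    ggplot2::theme_minimal()
}

#' Single-pass presentation of a pattern set
#'
#' Presents each pattern exactly once, in order, with carry-over chained and
#' learning off — the design used to score intention for every respondent of
#' an input set. Records the state at the last settling cycle.
#'
#' @inheritParams run_condition
#' @param patterns Pattern tibble; presentation order = row order.
#' @param keep_activations If `TRUE`, attach the full matrix of recorded
#'   visible-unit activations as the `"activations"` attribute.
#' @return A tibble with one row per pattern: `pattern`, `intend_mean`,
#'   `notintend_mean`.
#' @export
run_single_pass <- function(weights, patterns, clamp = 0.5, n_cycles = 9,
                            kappa = 0.1, rest = 0.5, gain = 10, eps = 1e-6,
                            keep_activations = FALSE) {
  stopifnot(inherits(weights, "intent_weights"))
  topo <- weights$topology
  pm <- pattern_matrix(patterns)
  K <- nrow(pm)
  if (K < 1) stop("`patterns` is empty.", call. = FALSE)
  im <- numeric(K)
  nm <- numeric(K)
  acts <- if (keep_activations) {
    matrix(NA_real_, K, length(topo$visible),
           dimnames = list(NULL, topo$unit_labels[topo$visible]))
  }
  prev_final <- NULL
  for (k in seq_len(K)) {
    init <- carryover_state(prev_final, kappa = kappa, rest = rest,
                            n_units = topo$n_units)
    traj <- settle(weights, pm[k, ], clamp, n_cycles = n_cycles, init = init,
                   rest = rest, gain = gain, eps = eps)
    final <- traj[n_cycles, ]
    im[k] <- mean(final[topo$intend])
    nm[k] <- mean(final[topo$notintend])
    if (keep_activations) acts[k, ] <- final[topo$visible]
    prev_final <- final
  }
  out <- tibble::tibble(pattern = seq_len(K), intend_mean = im,
                        notintend_mean = nm)
  if (keep_activations) attr(out, "activations") <- acts
  out
}
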