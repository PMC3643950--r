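#' Logistic unit activation with range restriction
#'
#' The squashing function applied to every unit's net input: a logistic with
#' configurable gain, with the output restricted to the open interval (0, 1)
#' by clipping to `[eps, 1 - eps]`.
#'
#' @param net Net input (vectorized).
#' @param gain Logistic gain (slope at the midpoint is `gain / 4`); must be
#'   positive. The default of 10 is the package's reading of the model's
#'   "modified" logistic: it makes a clamped external bit (net contribution
#'   0.5 under strong clamping) nearly decisive for its unit, so the settling
#'   dynamics can binarize.
#' @param eps Clipping margin keeping activations strictly inside (0, 1).
#' @return Activations in `[eps, 1 - eps]`.
#' @examples
#' unit_activation(0) # 0.5
#' @export
unit_activation <- function(net, gain = 10, eps = 1e-6) {
  if (gain <= 0) stop("`gain` must be positive.", call. = FALSE)
  pmin(pmax(stats::plogis(gain * net), eps), 1 - eps)
}

#' Net input to every unit
#'
#' For unit `j` the net input is the weighted sum of incoming activations plus
#' the bias, plus — for visible units only — the external constraint term
#' `clamp * x_j`, where `x_j` is the corresponding component of the external
#' input pattern. The clamp strength acts as the connection weight from each
#' external input bit to its visible unit (soft clamping); hidden units
#' receive no external input.
#'
#' @param activations Numeric vector of current activations (one per unit).
#' @param weights An `intent_weights` object.
#' @param external Binary external vector of length `2 * n_beliefs` (intend
#'   bank bits then not-intend bank bits).
#' @param clamp Clamp strength in `[0, 1]`.
#' @return Numeric vector of net inputs, one per unit.
#' @export
net_input <- function(activations, weights, external, clamp) {
  topo <- weights$topology
  if (length(activations) != topo$n_units) {
    stop("`activations` must have one entry per unit (", topo$n_units, ").",
         call. = FALSE)
  }
  if (length(external) != 2L * topo$n_beliefs) {
    stop("`external` must have length ", 2L * topo$n_beliefs, ".", call. = FALSE)
  }
  net <- drop(weights$W %*% activations) + weights$bias
  net[topo$visible] <- net[topo$visible] + clamp * external
  net
}

#' Synchronous settling
#'
#' Runs the relaxation procedure: starting from `init`, every cycle computes
#' all net inputs from the previous cycle's activations and then updates every
#' unit simultaneously through [unit_activation()]. The state after cycle 9
#' (the default last cycle) is the one read out in the simulations.
#'
#' @inheritParams net_input
#' @param n_cycles Number of synchronous update cycles (default 9).
#' @param init Initial activation vector; defaults to the resting level
#'   `rest` for every unit (the first pattern of a run). Use
#'   [carryover_state()] to chain patterns.
#' @param rest Resting activation (the logistic of zero net input, 0.5).
#' @param gain,eps Passed to [unit_activation()].
#' @return A matrix with `n_cycles` rows (cycle 1 ... `n_cycles`) and one
#'   column per unit: the settling trajectory.
#' @export
settle <- function(weights, external, clamp, n_cycles = 9, init = NULL,
                   rest = 0.5, gain = 10, eps = 1e-6) {
  topo <- weights$topology
  if (n_cycles < 1) stop("`n_cycles` must be >= 1.", call. = FALSE)
  if (is.null(init)) init <- rep(rest, topo$n_units)
  if (length(init) != topo$n_units) {
    stop("`init` must have one entry per unit.", call. = FALSE)
  }
  ext_term <- numeric(topo$n_units)
  ext_term[topo$visible] <- clamp * external
  traj <- matrix(NA_real_, n_cycles, topo$n_units,
                 dimnames = list(NULL, topo$unit_labels))
  a <- init
  for (t in seq_len(n_cycles)) {
    net <- drop(weights$W %*% a) + weights$bias + ext_term
    a <- unit_activation(net, gain = gain, eps = eps)
    traj[t, ] <- a
  }
  traj
}

#' Carry-over of activation between input patterns
#'
#' A small portion of the activation at the end of one pattern's settling is
#' carried over into the initial state for the next pattern:
#' `init = rest + kappa * (prev_final - rest)`. With `kappa = 0` the network
#' restarts from rest; with `kappa = 1` the previous final state is copied.
#'
#' @param prev_final Final activation vector of the previous pattern, or
#'   `NULL` for the first pattern of a run.
#' @param kappa Carry-over proportion in `[0, 1]` (default 0.1).
#' @param rest Resting activation level.
#' @param n_units Number of units (needed only when `prev_final` is `NULL`).
#' @return Initial activation vector for the next pattern's settling.
#' @export
carryover_state <- function(prev_final, kappa = 0.1, rest = 0.5,
                            n_units = length(prev_final)) {
  if (kappa < 0 || kappa > 1) stop("`kappa` must be in [0, 1].", call. = FALSE)
  if (is.null(prev_final)) return(rep(rest, n_units))
  rest + kappa * (prev_final - rest)
}
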