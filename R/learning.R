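#' Error of one settling trajectory against its target pattern
#'
#' Sums the per-unit discrepancy between the visible-unit activations and the
#' binary target pattern over the listed settling cycles (the default window
#' is cycles 7-9). Hidden units contribute no error. The sum-squared measure
#' is `sum((a - y)^2)`; cross-entropy is `-sum(y log a + (1-y) log(1-a))`.
#'
#' @param trajectory Settling trajectory from [settle()].
#' @param target Binary target vector over the visible units (the input
#'   pattern itself: the network is an auto-associator).
#' @param error_cycles Cycle indices at which error is evaluated.
#' @param visible Indices of the visible units within the trajectory columns.
#' @param measure `"sse"` (sum-squared, default) or `"cross-entropy"`.
#' @return Non-negative scalar error.
#' @export
pattern_error <- function(trajectory, target,
                          error_cycles = 7:9,
                          visible = seq_along(target),
                          measure = c("sse", "cross-entropy")) {
  measure <- match.arg(measure)
  if (max(error_cycles) > nrow(trajectory)) {
    stop("`error_cycles` exceed the trajectory length.", call. = FALSE)
  }
  a <- trajectory[error_cycles, visible, drop = FALSE]
  y <- matrix(target, nrow = length(error_cycles), ncol = length(target),
              byrow = TRUE)
  if (measure == "sse") {
    sum((a - y)^2)
  } else {
    -sum(y * log(a) + (1 - y) * log(1 - a))
  }
}

# Forward pass over an ordered set of patterns with carry-over chaining.
# Returns the list of trajectories (each (n_cycles+1) x n_units, row 1 = the
# initial state) and the total error.
forward_chain <- function(weights, patterns, clamp, n_cycles, error_cycles,
                          kappa, rest, gain, eps, measure = "sse") {
  topo <- weights$topology
  n <- topo$n_units
  K <- nrow(patterns)
  trajs <- vector("list", K)
  total_error <- 0
  prev_final <- NULL
  for (k in seq_len(K)) {
    init <- carryover_state(prev_final, kappa = kappa, rest = rest, n_units = n)
    traj <- settle(weights, patterns[k, ], clamp, n_cycles = n_cycles,
                   init = init, rest = rest, gain = gain, eps = eps)
    trajs[[k]] <- rbind(init, traj, deparse.level = 0)
    total_error <- total_error +
      pattern_error(traj, patterns[k, ], error_cycles = error_cycles,
                    visible = topo$visible, measure = measure)
    prev_final <- traj[n_cycles, ]
  }
  list(trajectories = trajs, error = total_error)
}

#' Batch gradient of the settling error
#'
#' Backpropagation through the unrolled synchronous settling (through time),
#' injecting the sum-squared output error at the configured cycles on the
#' visible units. The backward pass also propagates through the carry-over
#' link between consecutive patterns (the initial state of pattern k+1 depends
#' on the final state of pattern k scaled by `kappa`), so the gradient is
#' exact for the whole presentation chain. Gradients on structurally absent
#' connections and on the frozen inter-valence links are identically zero.
#'
#' @param weights An `intent_weights` object.
#' @param patterns Matrix of binary input patterns, one row per pattern,
#'   `2 * n_beliefs` columns (see [pattern_matrix()]).
#' @param clamp Clamp strength during training (default 0.5).
#' @param n_cycles Settling cycles per pattern (default 9).
#' @param error_cycles Cycles at which error is injected (default 7:9).
#' @param kappa Carry-over proportion across patterns within the batch.
#' @param rest,gain,eps Settling parameters, as in [settle()].
#' @param measure Error measure, `"sse"` or `"cross-entropy"` (see
#'   [pattern_error()]).
#' @return List with `grad_W` (matrix conformable with `weights$W`), `grad_b`
#'   (bias gradient vector), and `error` (total batch error).
#' @export
network_gradient <- function(weights, patterns, clamp = 0.5, n_cycles = 9,
                             error_cycles = 7:9, kappa = 0.1, rest = 0.5,
                             gain = 10, eps = 1e-6,
                             measure = c("sse", "cross-entropy")) {
  measure <- match.arg(measure)
  topo <- weights$topology
  n <- topo$n_units
  if (!is.matrix(patterns) || ncol(patterns) != 2L * topo$n_beliefs) {
    stop("`patterns` must be a matrix with ", 2L * topo$n_beliefs,
         " columns.", call. = FALSE)
  }
  K <- nrow(patterns)
  if (K < 1) stop("`patterns` must contain at least one pattern.", call. = FALSE)

  fwd <- forward_chain(weights, patterns, clamp, n_cycles, error_cycles,
                       kappa, rest, gain, eps, measure = measure)
  grad_W <- matrix(0, n, n)
  grad_b <- numeric(n)
  Wt <- t(weights$W)
  in_error <- rep(FALSE, n_cycles)
  in_error[error_cycles] <- TRUE

  # delta0_next: dE/d(initial state of pattern k+1); flows back into the final
  # state of pattern k through the carry-over scaling.
  delta0_next <- NULL
  for (k in rev(seq_len(K))) {
    traj <- fwd$trajectories[[k]] # rows: init, cycle 1..n_cycles
    y <- rep(0, n)
    y[topo$visible] <- patterns[k, ]
    delta <- numeric(n) # dE/da at current cycle
    if (!is.null(delta0_next)) delta <- delta + kappa * delta0_next
    for (t in n_cycles:1) {
      a_t <- traj[t + 1L, ]
      if (in_error[t]) {
        e <- numeric(n)
        av <- a_t[topo$visible]
        yv <- y[topo$visible]
        e[topo$visible] <- if (measure == "sse") {
          2 * (av - yv)
        } else {
          (av - yv) / (av * (1 - av)) # dE/da for cross-entropy
        }
        delta <- delta + e
      }
      g <- delta * gain * a_t * (1 - a_t) # dE/dnet at cycle t
      a_prev <- traj[t, ]
      grad_W <- grad_W + tcrossprod(g, a_prev)
      grad_b <- grad_b + g
      delta <- drop(Wt %*% g)
    }
    delta0_next <- delta
  }
  trainable <- topo$mask & !topo$fixed
  grad_W[!trainable] <- 0
  list(grad_W = unname(grad_W), grad_b = unname(grad_b), error = fwd$error)
}

#' Train the internal processing constraints
#'
#' Batch training of the intention network by the generalized delta rule:
#' within each epoch all patterns are presented in fixed order (the forward
#' passes chained by carry-over), the error on the visible units at the late
#' settling cycles is backpropagated through the unrolled settling, gradients
#' are accumulated, and one weight update is applied at the end of the epoch.
#' Targets are the input patterns themselves (auto-association). The paired
#' inter-valence links stay frozen throughout; training is driven by the
#' remaining connections and the biases.
#'
#' @param weights Starting `intent_weights`, typically from [init_weights()].
#' @param patterns Binary pattern matrix (rows = patterns), e.g. from
#'   [pattern_matrix()] on a generated pattern set.
#' @param n_epochs Number of batch epochs (default 200).
#' @param learning_rate Step size of the batch update.
#' @param momentum Momentum coefficient in `[0, 1)` (default 0, i.e. none).
#' @param clamp Clamp strength during training (default 0.5).
#' @param n_cycles,error_cycles,kappa,rest,gain,eps,measure As in
#'   [network_gradient()].
#' @return An object of class `intent_fit`: list with the trained `weights`,
#'   a `trace` tibble (`epoch`, `error`), and the training settings.
#'   [generics::tidy()] returns the trace; [generics::glance()] a one-row
#'   summary.
#' @examples
#' topo <- make_topology(3, 2)
#' w0 <- init_weights(topo, seed = 1)
#' pats <- pattern_matrix(bernoulli_patterns(4, p = 0.5, seed = 2, n_beliefs = 3))
#' fit <- train_weights(w0, pats, n_epochs = 10)
#' @export
train_weights <- function(weights, patterns, n_epochs = 200,
                          learning_rate = 2e-4, momentum = 0, clamp = 0.5,
                          n_cycles = 9, error_cycles = 7:9, kappa = 0.1,
                          rest = 0.5, gain = 10, eps = 1e-6,
                          measure = c("sse", "cross-entropy")) {
  measure <- match.arg(measure)
  stopifnot(inherits(weights, "intent_weights"))
  if (learning_rate < 0) stop("`learning_rate` must be >= 0.", call. = FALSE)
  if (momentum < 0 || momentum >= 1) {
    stop("`momentum` must be in [0, 1).", call. = FALSE)
  }
  if (max(error_cycles) > n_cycles) {
    stop("`error_cycles` must lie within 1..n_cycles.", call. = FALSE)
  }
  W <- weights$W
  b <- weights$bias
  vel_W <- matrix(0, nrow(W), ncol(W))
  vel_b <- numeric(length(b))
  errors <- numeric(n_epochs)
  cur <- weights
  for (ep in seq_len(n_epochs)) {
    g <- network_gradient(cur, patterns, clamp = clamp, n_cycles = n_cycles,
                          error_cycles = error_cycles, kappa = kappa,
                          rest = rest, gain = gain, eps = eps,
                          measure = measure)
    if (!is.finite(g$error)) {
      stop("Training diverged (non-finite error) at epoch ", ep, ".",
           call. = FALSE)
    }
    errors[ep] <- g$error
    vel_W <- momentum * vel_W - learning_rate * g$grad_W
    vel_b <- momentum * vel_b - learning_rate * g$grad_b
    W <- W + vel_W
    b <- b + vel_b
    cur <- structure(
      list(W = W, bias = b, fixed_value = weights$fixed_value,
           topology = weights$topology),
      class = "intent_weights"
    )
  }
  structure(
    list(weights = cur,
         trace = tibble::tibble(epoch = seq_len(n_epochs), error = errors),
         settings = list(n_epochs = n_epochs, learning_rate = learning_rate,
                         momentum = momentum, clamp = clamp,
                         n_cycles = n_cycles, error_cycles = error_cycles,
                         kappa = kappa, rest = rest, gain = gain, eps = eps,
                         measure = measure),
         n_patterns = nrow(patterns)),
    class = "intent_fit"
  )
}

#' @export
print.intent_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<intent_fit> ", n, " epochs on ", x$n_patterns, " patterns; error ",
      format(x$trace$error[1], digits = 4), " -> ",
      format(x$trace$error[n], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training trace
#'
#' @param x An `intent_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per epoch (`epoch`, `error`).
#' @export
tidy.intent_fit <- function(x, ...) x$trace

#' One-row training summary
#'
#' @param x An `intent_fit` object.
#' @param ... Unused.
#' @return A tibble with the epoch count, initial and final batch error, and
#'   the learning settings.
#' @export
glance.intent_fit <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(
    n_epochs = n,
    n_patterns = x$n_patterns,
    initial_error = x$trace$error[1],
    final_error = x$trace$error[n],
    learning_rate = x$settings$learning_rate,
    momentum = x$settings$momentum,
    clamp = x$settings$clamp,
    kappa = x$settings$kappa
  )
}

#' Plot the training error trajectory
#'
#' @param object An `intent_fit` object.
#' @param ... Unused.
#' @return A ggplot of batch error against epoch.
#' @export
autoplot.intent_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$epoch, y = .data$error)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Batch error (sum squared)",
                  title = "Generalized delta rule training") +
    ggplot2::theme_minimal()
}
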