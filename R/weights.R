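#' Initialize a weight set
#'
#' Creates the full set of connection strengths for an intention network.
#' Trainable entries (all allowed connections except the paired inter-valence
#' links) are drawn i.i.d. uniform on `[-scale, scale]`; the paired
#' inter-valence links are frozen at `fixed_value` (an inhibitory constraint,
#' -0.20 by default) in both directions; structurally absent connections are
#' exactly zero. Biases are trainable and start at zero.
#'
#' @param topology An [make_topology()] object.
#' @param seed Integer seed; the same seed always yields the same weights.
#' @param scale Half-width of the uniform initialization interval. `scale = 0`
#'   gives exactly zero trainable weights.
#' @param fixed_value Strength of the frozen inter-valence links.
#' @return An object of class `intent_weights`: list with `W` (matrix, entry
#'   `[j, i]` = strength of the connection from unit `i` to unit `j`), `bias`
#'   (numeric vector), and the `topology`.
#' @examples
#' w <- init_weights(make_topology(3, 2), seed = 1)
#' w$W[4, 1] # inter-valence link of belief 1: -0.2
#' @export
init_weights <- function(topology, seed = 1L, scale = 0.1, fixed_value = -0.2) {
  stopifnot(inherits(topology, "intent_topology"))
  if (!is.numeric(scale) || scale < 0) {
    stop("`scale` must be a non-negative number.", call. = FALSE)
  }
  n <- topology$n_units
  W <- matrix(0, n, n)
  trainable <- topology$mask & !topology$fixed
  set.seed(as.integer(seed))
  W[trainable] <- stats::runif(sum(trainable), -scale, scale)
  W[topology$fixed] <- fixed_value
  structure(
    list(W = W, bias = numeric(n), fixed_value = fixed_value,
         topology = topology),
    class = "intent_weights"
  )
}

#' @export
print.intent_weights <- function(x, ...) {
  cat("<intent_weights> ", x$topology$n_units, " units; ",
      sum(x$topology$mask & !x$topology$fixed), " trainable connections; ",
      "inter-valence links fixed at ", format(x$fixed_value), "\n", sep = "")
  invisible(x)
}

#' Write / read a weight set as JSON
#'
#' Serializes all connection strengths, biases, and the topology dimensions to
#' a JSON file; the round trip is exact (full double precision).
#'
#' @param weights An `intent_weights` object.
#' @param path File path.
#' @return `write_weights` returns `path` invisibly; `read_weights` returns
#'   the reconstructed `intent_weights`.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "intent_weights"))
  topo <- weights$topology
  obj <- list(
    n_beliefs = topo$n_beliefs,
    n_hidden_per_bank = topo$n_hidden_per_bank,
    fixed_value = weights$fixed_value,
    unit_labels = topo$unit_labels,
    bias = weights$bias,
    W = as.vector(weights$W) # column-major
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- make_topology(obj$n_beliefs, obj$n_hidden_per_bank)
  n <- topo$n_units
  W <- matrix(obj$W, n, n)
  if (!all(W[!topo$mask] == 0)) {
    stop("Serialized weights carry strengths on structurally absent connections.",
         call. = FALSE)
  }
  structure(
    list(W = W, bias = obj$bias, fixed_value = obj$fixed_value,
         topology = topo),
    class = "intent_weights"
  )
}
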