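#' Paired-valence auto-associator topology
#'
#' Builds the connectivity structure of the intention network. Each of the
#' `n_beliefs` beliefs is split between two visible units: one carrying its
#' positive valence (the *intend* bank) and one carrying its negative valence
#' (the *not-intend* bank). Within each valence bank the belief units are
#' fully interconnected in both directions; between banks the only
#' visible-visible connections are the paired inter-valence links joining the
#' two units of the same belief. Two banks of hidden units are attached, one
#' per valence bank: every hidden unit in bank A connects bidirectionally to
#' every intend-bank unit (and to nothing else), and hidden bank B likewise to
#' the not-intend bank. No unit is self-connected and there are no
#' hidden-hidden connections. Every unit additionally receives a trainable
#' bias, represented as a weight from a constant-on unit.
#'
#' Unit indices are laid out as: intend bank `1..n_beliefs`, not-intend bank
#' `n_beliefs + (1..n_beliefs)`, hidden bank A, then hidden bank B.
#'
#' @param n_beliefs Number of beliefs (default 14: nine outcome beliefs plus
#'   five normative beliefs).
#' @param n_hidden_per_bank Number of hidden units attached to each valence
#'   bank (default 10).
#' @return An object of class `intent_topology`: a list with the unit counts,
#'   index vectors (`intend`, `notintend`, `hidden_a`, `hidden_b`, `visible`),
#'   the logical connectivity `mask` (entry `[j, i]` is `TRUE` when a directed
#'   connection from unit `i` to unit `j` exists), and the logical
#'   `fixed` mask marking the paired inter-valence links whose strength is
#'   frozen rather than learned.
#' @examples
#' topo <- make_topology(14, 10)
#' topo$n_units # 48
#' @export
make_topology <- function(n_beliefs = 14, n_hidden_per_bank = 10) {
  if (!is.numeric(n_beliefs) || length(n_beliefs) != 1 || n_beliefs < 1 ||
      n_beliefs != round(n_beliefs)) {
    stop("`n_beliefs` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(n_hidden_per_bank) || length(n_hidden_per_bank) != 1 ||
      n_hidden_per_bank < 0 || n_hidden_per_bank != round(n_hidden_per_bank)) {
    stop("`n_hidden_per_bank` must be a non-negative integer.", call. = FALSE)
  }
  nb <- as.integer(n_beliefs)
  nh <- as.integer(n_hidden_per_bank)
  n_units <- 2L * nb + 2L * nh

  intend    <- seq_len(nb)
  notintend <- nb + seq_len(nb)
  hidden_a  <- if (nh > 0) 2L * nb + seq_len(nh) else integer(0)
  hidden_b  <- if (nh > 0) 2L * nb + nh + seq_len(nh) else integer(0)

  mask <- matrix(FALSE, n_units, n_units)
  # fully interconnected visible units within each valence bank
  mask[intend, intend] <- TRUE
  mask[notintend, notintend] <- TRUE
  # paired inter-valence links: belief i positive <-> belief i negative
  fixed <- matrix(FALSE, n_units, n_units)
  for (i in seq_len(nb)) {
    mask[notintend[i], intend[i]] <- TRUE
    mask[intend[i], notintend[i]] <- TRUE
    fixed[notintend[i], intend[i]] <- TRUE
    fixed[intend[i], notintend[i]] <- TRUE
  }
  # hidden banks: bidirectional full projection to their own visible bank only
  if (nh > 0) {
    mask[hidden_a, intend] <- TRUE
    mask[intend, hidden_a] <- TRUE
    mask[hidden_b, notintend] <- TRUE
    mask[notintend, hidden_b] <- TRUE
  }
  diag(mask) <- FALSE

  labels <- c(paste0("pos_", seq_len(nb)), paste0("neg_", seq_len(nb)),
              if (nh > 0) paste0("hA_", seq_len(nh)),
              if (nh > 0) paste0("hB_", seq_len(nh)))

  structure(
    list(n_beliefs = nb, n_hidden_per_bank = nh, n_units = n_units,
         intend = intend, notintend = notintend,
         hidden_a = hidden_a, hidden_b = hidden_b,
         visible = c(intend, notintend),
         mask = mask, fixed = fixed, unit_labels = labels),
    class = "intent_topology"
  )
}

#' @export
print.intent_topology <- function(x, ...) {
  cat("<intent_topology> ", x$n_beliefs, " beliefs x 2 valence banks + 2 x ",
      x$n_hidden_per_bank, " hidden units (", x$n_units, " units, ",
      sum(x$mask), " directed connections)\n", sep = "")
  invisible(x)
}
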