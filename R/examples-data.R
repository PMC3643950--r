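#' Reference cross-tabulation of empirical by model intention
#'
#' The 4 x 4 cross-tabulation of the empirical intention item (rows, 1 = NO!
#' ... 4 = YES!) by the model's intention category (columns) for the reference
#' sample of 105 female 10th-grade virgins. It is the worked example for the
#' exact contingency-table inference: its Freeman-Halton two-sided tail
#' probability is 0.0004355.
#'
#' @return An `intent_crosstab` matrix (rows = empirical intention, columns =
#'   model intention).
#' @examples
#' tab <- f10v_reference_crosstab()
#' freeman_halton_p(tab)$p
#' @export
f10v_reference_crosstab <- function() {
  out <- matrix(
    c(23L, 27L, 0L, 0L,
      10L, 26L, 0L, 0L,
      0L, 17L, 1L, 0L,
      0L,  1L, 0L, 0L),
    nrow = 4, byrow = TRUE,
    dimnames = list(empirical = paste(1:4), model = paste(1:4))
  )
  class(out) <- c("intent_crosstab", class(out))
  out
}
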