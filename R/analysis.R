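#' Continuous intention score and its 4-level category
#'
#' The intention score of a recorded network state is the mean activation of
#' the intend bank minus the mean activation of the not-intend bank, a
#' continuous measure in (-1, 1): negative values represent not intending,
#' positive intending. `intention_scores()` appends the score and its category
#' to a single-pass result; `categorize_intention()` bins scores with the
#' cut-points (-1, -0.5] = 1, (-0.5, 0] = 2, (0, 0.5] = 3, (0.5, 1) = 4,
#' aligning the model measure with the 4-level survey item
#' (1 = NO!, 2 = no, 3 = yes, 4 = YES!). Boundary scores belong to the lower
#' category (a score of exactly -0.5 is category 1; exactly 0 is category 2).
#'
#' @param states A tibble with `intend_mean` and `notintend_mean` columns,
#'   e.g. from [run_single_pass()].
#' @return `intention_scores()`: the input tibble with `score` and
#'   `model_intention` columns added.
#' @export
intention_scores <- function(states) {
  dplyr::mutate(states,
                score = .data$intend_mean - .data$notintend_mean,
                model_intention = categorize_intention(.data$score))
}

#' @rdname intention_scores
#' @param score Numeric scores in `[-1, 1]`.
#' @return `categorize_intention()`: integer categories 1-4.
#' @export
categorize_intention <- function(score) {
  if (any(score < -1 | score > 1)) {
    stop("Intention scores must lie in [-1, 1].", call. = FALSE)
  }
  cats <- as.integer(cut(score, breaks = c(-1, -0.5, 0, 0.5, 1),
                         right = TRUE, include.lowest = TRUE))
  cats
}

#' Cross-tabulate empirical by model intention
#'
#' Counts respondents by (empirical intention, model intention) pair over the
#' full 4 x 4 category grid.
#'
#' @param data A data frame holding both category columns.
#' @param empirical,model Column names (character) of the empirical and model
#'   intention categories (integers 1-4).
#' @return A 4 x 4 integer matrix of class `intent_crosstab`; rows = empirical
#'   intention 1-4, columns = model intention 1-4.
#' @export
intention_crosstab <- function(data, empirical = "intention",
                               model = "model_intention") {
  e <- data[[empirical]]
  m <- data[[model]]
  if (length(e) != length(m)) stop("Unequal category lengths.", call. = FALSE)
  if (any(!e %in% 1:4) || any(!m %in% 1:4)) {
    stop("Categories must be integers in 1..4.", call. = FALSE)
  }
  tab <- table(factor(e, levels = 1:4), factor(m, levels = 1:4))
  out <- matrix(as.integer(tab), 4, 4,
                dimnames = list(empirical = paste(1:4),
                                model = paste(1:4)))
  class(out) <- c("intent_crosstab", class(out))
  out
}

# log multivariate hypergeometric mass of a table given both margins:
# log[ prod(r_i!) prod(c_j!) / (N! prod(n_ij!)) ]
log_table_probability <- function(tab) {
  r <- rowSums(tab)
  co <- colSums(tab)
  sum(lgamma(r + 1)) + sum(lgamma(co + 1)) - lgamma(sum(tab) + 1) -
    sum(lgamma(tab + 1))
}

#' Exact point probability of a contingency table given its margins
#'
#' The multivariate hypergeometric probability of observing exactly this table
#' conditional on both margins, computed with log-factorials:
#' `prod(rowtot!) * prod(coltot!) / (N! * prod(cell!))`. For a 2 x 2 table
#' this is the classical hypergeometric point mass.
#'
#' @param tab Non-negative integer matrix (any R x C).
#' @return The point probability.
#' @examples
#' exact_point_probability(matrix(c(3, 1, 1, 3), 2))
#' @export
exact_point_probability <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("`tab` must hold non-negative integers.", call. = FALSE)
  }
  exp(log_table_probability(tab))
}

# Enumerate all non-negative integer tables with the given margins, calling
# `fun(tab)` on each. Rows are filled one at a time, cells left to right; each
# cell value v is bounded below by what the remaining columns of the row
# cannot absorb and above by the remaining column capacity, so the recursion
# visits no dead branches (every leaf is a valid table).
enumerate_tables <- function(row_sums, col_sums, fun, guard = 2e6) {
  R <- length(row_sums)
  C <- length(col_sums)
  tab <- matrix(0L, R, C)
  count <- 0L
  fill_row <- function(i, rem_cols) {
    if (i > R) {
      count <<- count + 1L
      if (count > guard) {
        stop("Enumeration exceeds the guard limit (", format(guard),
             " tables); use the Monte-Carlo mode.", call. = FALSE)
      }
      fun(tab)
      return(invisible())
    }
    fill_cell <- function(j, rem_row, rem_cols) {
      if (j == C) {
        tab[i, C] <<- rem_row # bounds guarantee rem_row <= rem_cols[C]
        rc <- rem_cols
        rc[C] <- rc[C] - rem_row
        fill_row(i + 1L, rc)
        return(invisible())
      }
      tail_cap <- sum(rem_cols[(j + 1L):C])
      lo <- max(0L, rem_row - tail_cap)
      hi <- min(rem_row, rem_cols[j])
      for (v in lo:hi) {
        tab[i, j] <<- v
        rc <- rem_cols
        rc[j] <- rc[j] - v
        fill_cell(j + 1L, rem_row - v, rc)
      }
      tab[i, j] <<- 0L
    }
    fill_cell(1L, row_sums[i], rem_cols)
  }
  fill_row(1L, col_sums)
  invisible(count)
}

#' Freeman-Halton exact test for an R x C table
#'
#' The two-sided tail generalization of Fisher's exact test: the sum of the
#' conditional (multivariate hypergeometric) probabilities of every table with
#' the observed margins whose point probability does not exceed that of the
#' observed table. `mode = "enumerate"` sums over a complete enumeration of
#' margin-consistent tables; `mode = "montecarlo"` estimates the same quantity
#' by sampling tables with fixed margins (Patefield's algorithm via
#' [stats::r2dtable()]).
#'
#' @param tab Observed non-negative integer table.
#' @param mode `"enumerate"` (exact) or `"montecarlo"`.
#' @param n_mc Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo mode.
#' @param guard Maximum number of tables the enumeration may visit before
#'   refusing (switch to Monte Carlo above it).
#' @return A list of class `freeman_halton`: `p` (tail probability),
#'   `point_probability` of the observed table, `mode`, `n_tables`
#'   (enumerated count) or `n_mc`, and `mc_se` (Monte-Carlo standard error,
#'   `NA` for enumeration).
#' @examples
#' tab <- matrix(c(8, 2, 3, 9), 2)
#' freeman_halton_p(tab)$p
#' @export
freeman_halton_p <- function(tab, mode = c("enumerate", "montecarlo"),
                             n_mc = 1e5, seed = 1L, guard = 2e6) {
  mode <- match.arg(mode)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("`tab` must hold non-negative integers.", call. = FALSE)
  }
  lp_obs <- log_table_probability(tab)
  # relative tolerance for "as or less probable", guarding rounding noise
  cutoff <- lp_obs + 1e-7
  if (mode == "enumerate") {
    acc <- new.env()
    acc$lp <- -Inf
    acc$n <- 0L
    enumerate_tables(rowSums(tab), colSums(tab), function(t2) {
      lp <- log_table_probability(t2)
      if (lp <= cutoff) {
        acc$lp <- if (acc$lp == -Inf) lp else
          max(acc$lp, lp) + log1p(exp(-abs(acc$lp - lp)))
        acc$n <- acc$n + 1L
      }
    }, guard = guard)
    structure(list(p = exp(acc$lp), point_probability = exp(lp_obs),
                   mode = mode, n_tables = acc$n, mc_se = NA_real_),
              class = "freeman_halton")
  } else {
    set.seed(as.integer(seed))
    r <- rowSums(tab)
    co <- colSums(tab)
    # r2dtable requires positive margins; drop empty rows/columns (their cells
    # are forced to zero and do not change any table probability)
    keep_r <- r > 0
    keep_c <- co > 0
    draws <- stats::r2dtable(n_mc, r[keep_r], co[keep_c])
    hits <- vapply(draws, function(t2) log_table_probability(t2) <= cutoff,
                   logical(1))
    phat <- mean(hits)
    structure(list(p = phat, point_probability = exp(lp_obs),
                   mode = mode, n_mc = n_mc,
                   mc_se = sqrt(phat * (1 - phat) / n_mc)),
              class = "freeman_halton")
  }
}

#' @export
print.freeman_halton <- function(x, ...) {
  cat("Freeman-Halton exact test (", x$mode, ")\n", sep = "")
  cat("  two-sided tail p  =", format(x$p, digits = 7), "\n")
  cat("  point probability =", format(x$point_probability, digits = 7), "\n")
  if (x$mode == "montecarlo") {
    cat("  MC tables =", x$n_mc, " (SE ", format(x$mc_se, digits = 3), ")\n")
  } else {
    cat("  tables in tail =", x$n_tables, "\n")
  }
  invisible(x)
}

#' Per-category summaries of the intention score
#'
#' Mean, standard error (sample SD over the square root of n; undefined and
#' reported as `NA` for singleton categories) and count of the continuous
#' intention score within each level of the empirical intention item.
#'
#' @param data A data frame of scored respondents.
#' @param score,category Column names of the continuous score and the
#'   empirical category.
#' @return A tibble with one row per observed category: `category`, `mean`,
#'   `se`, `n`.
#' @export
group_stats <- function(data, score = "score", category = "intention") {
  tibble::tibble(category = data[[category]], s = data[[score]]) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean = mean(.data$s),
      se = ifelse(dplyr::n() > 1, stats::sd(.data$s) / sqrt(dplyr::n()),
                  NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category)
}

#' Dummy-coded regression of intention score on empirical intention
#'
#' Ordinary least squares of the continuous model intention score on indicator
#' variables for the non-reference levels of the empirical intention item
#' (reference = category 1, "NO!", by default). By the one-way ANOVA identity,
#' the intercept equals the reference-category mean and each dummy coefficient
#' the difference between that category's mean and the reference mean.
#'
#' @param data A data frame of scored respondents.
#' @param score,category Column names, as in [group_stats()].
#' @param reference Reference category.
#' @return An object of class `intent_regression` wrapping the [stats::lm()]
#'   fit, with [generics::tidy()] (coefficient table) and [generics::glance()]
#'   (adjusted R-squared, omnibus F and its degrees of freedom) methods.
#' @export
dummy_regression <- function(data, score = "score", category = "intention",
                             reference = 1) {
  y <- data[[score]]
  g <- data[[category]]
  lev <- sort(unique(g))
  if (length(lev) < 2) {
    stop("At least two categories are required.", call. = FALSE)
  }
  if (!reference %in% lev) {
    stop("`reference` category not present in the data.", call. = FALSE)
  }
  f <- stats::relevel(factor(g, levels = lev), ref = as.character(reference))
  fit <- stats::lm(y ~ f)
  structure(list(fit = fit, reference = reference, levels = lev,
                 n = length(y)),
            class = "intent_regression")
}

#' @export
print.intent_regression <- function(x, ...) {
  cat("Dummy-coded OLS of intention score on empirical intention",
      "(reference =", x$reference, ")\n")
  print(tidy(x))
  g <- glance(x)
  cat(sprintf("Adj. R-sq = %.3f; omnibus F(%d, %d) = %.2f, p = %.3g\n",
              g$adj_r_squared, g$df_model, g$df_residual, g$f_statistic,
              g$p_value))
  invisible(x)
}

#' @rdname dummy_regression
#' @param x An `intent_regression` object.
#' @param ... Unused.
#' @export
tidy.intent_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  term <- rownames(s)
  term[1] <- "intercept"
  term <- sub("^f", "category_", term)
  tibble::tibble(term = term, estimate = unname(s[, 1]),
                 std_error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p_value = unname(s[, 4]))
}

#' @rdname dummy_regression
#' @export
glance.intent_regression <- function(x, ...) {
  s <- summary(x$fit)
  fs <- s$fstatistic
  tibble::tibble(
    adj_r_squared = s$adj.r.squared,
    r_squared = s$r.squared,
    f_statistic = unname(fs[1]),
    df_model = as.integer(fs[2]),
    df_residual = as.integer(fs[3]),
    p_value = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    n = x$n
  )
}
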