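test_that("intention score is the bank-mean difference", {
  states <- tibble::tibble(pattern = 1:3,
                           intend_mean = c(0.999, 0.5, 0.2),
                           notintend_mean = c(0.001, 0.5, 0.9))
  sc <- intention_scores(states)
  expect_equal(sc$score, c(0.998, 0, -0.7))
  expect_equal(sc$model_intention, c(4L, 2L, 1L))

  # matches the direct two-mean subtraction on random full-width states
  set.seed(3)
  acts <- matrix(runif(28), 1)
  st <- tibble::tibble(intend_mean = mean(acts[1:14]),
                       notintend_mean = mean(acts[15:28]))
  expect_equal(intention_scores(st)$score,
               mean(acts[1:14]) - mean(acts[15:28]))
})

test_that("categorization uses half-open cut-points with lower-bin boundaries", {
  expect_equal(categorize_intention(-0.413), 2L)
  expect_equal(categorize_intention(-0.5), 1L)
  expect_equal(categorize_intention(0.25), 3L)
  expect_equal(categorize_intention(0), 2L)
  expect_equal(categorize_intention(0.5), 3L)
  expect_equal(categorize_intention(-1), 1L)
  expect_equal(categorize_intention(1), 4L)

  # machine-epsilon offsets fall on the documented side of each edge
  eps <- 1e-9
  expect_equal(categorize_intention(c(-0.5 - eps, -0.5 + eps)), c(1L, 2L))
  expect_equal(categorize_intention(c(-eps, eps)), c(2L, 3L))
  expect_equal(categorize_intention(c(0.5 - eps, 0.5 + eps)), c(3L, 4L))

  # partition: every admissible score lands in exactly one category
  s <- seq(-1, 1, by = 0.01)
  cats <- categorize_intention(s)
  expect_true(all(cats %in% 1:4))
  expect_false(anyNA(cats))

  expect_error(categorize_intention(1.01), "-1, 1")
})

test_that("cross-tabulation counts category pairs over the full 4x4 grid", {
  d <- tibble::tibble(intention = c(1, 1, 2), model_intention = c(1, 2, 2))
  tab <- intention_crosstab(d)
  expect_equal(dim(tab), c(4L, 4L))
  expect_equal(tab[1, 1], 1L)
  expect_equal(tab[1, 2], 1L)
  expect_equal(tab[2, 2], 1L)
  expect_equal(sum(tab), 3L)

  # nested-loop counting oracle on random categories
  set.seed(8)
  d2 <- tibble::tibble(intention = sample(1:4, 200, replace = TRUE),
                       model_intention = sample(1:4, 200, replace = TRUE))
  tab2 <- intention_crosstab(d2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(tab2[i, j],
                 sum(d2$intention == i & d2$model_intention == j))
  }
  expect_equal(sum(tab2), 200L)

  expect_error(intention_crosstab(tibble::tibble(intention = 1,
                                                 model_intention = 5)),
               "1..4")
})

test_that("point probability matches the 2x2 hypergeometric closed form", {
  set.seed(21)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    p <- exact_point_probability(tab)
    # classical hypergeometric point mass given both margins
    oracle <- stats::dhyper(tab[1, 1], rowSums(tab)[1], rowSums(tab)[2],
                            colSums(tab)[1])
    expect_equal(p, oracle, tolerance = 1e-12)
  }
  # a single nonzero row is forced by its margins
  expect_equal(exact_point_probability(rbind(c(3, 2, 5), c(0, 0, 0))), 1)
  expect_error(exact_point_probability(matrix(c(1, -1, 2, 3), 2)),
               "non-negative")
})

test_that("point probabilities sum to one over a complete enumeration", {
  tabs <- list(rbind(c(2, 1), c(1, 3)),
               rbind(c(3, 1, 2), c(0, 2, 2), c(2, 2, 0)),
               rbind(c(5, 0), c(1, 1), c(0, 4)))
  for (tab in tabs) {
    total <- 0
    n_tables <- intentnet:::enumerate_tables(rowSums(tab), colSums(tab),
      function(t2) total <<- total + exact_point_probability(t2))
    expect_equal(total, 1, tolerance = 1e-10)
    expect_gt(n_tables, 1)
  }
})

test_that("Freeman-Halton enumeration agrees with independent exact tests", {
  # 2x2: equals the hypergeometric two-sided tail (and fisher.test)
  set.seed(31)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    fh <- freeman_halton_p(tab)
    r1 <- rowSums(tab)[1]; r2 <- rowSums(tab)[2]; c1 <- colSums(tab)[1]
    support <- max(0, c1 - r2):min(r1, c1)
    dens <- stats::dhyper(support, r1, r2, c1)
    oracle <- sum(dens[dens <= dens[support == tab[1, 1]] * (1 + 1e-7)])
    expect_equal(fh$p, oracle, tolerance = 1e-9)
    expect_equal(fh$p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }

  # degenerate one-row table: the margins force the table
  expect_equal(freeman_halton_p(rbind(c(4, 1, 2), c(0, 0, 0)))$p, 1)

  # RxC case cross-checked against the network-algorithm implementation
  tab3 <- rbind(c(6, 2, 1), c(1, 5, 2), c(2, 1, 6))
  expect_equal(freeman_halton_p(tab3)$p, stats::fisher.test(tab3)$p.value,
               tolerance = 1e-7)

  # the guard refuses over-large enumerations and points to Monte Carlo
  expect_error(freeman_halton_p(tab3, guard = 10), "Monte-Carlo")
})

test_that("Monte-Carlo tail estimates agree with enumeration", {
  tab <- rbind(c(6, 2, 1), c(1, 5, 2), c(2, 1, 6))
  exact <- freeman_halton_p(tab)$p
  mc <- freeman_halton_p(tab, mode = "montecarlo", n_mc = 4e4, seed = 5)
  expect_lt(abs(mc$p - exact), 3 * mc$mc_se)
})

test_that("group statistics report mean, SE and n per category", {
  d <- tibble::tibble(score = c(0.1, 0.3, -0.2), intention = c(1, 1, 3))
  gs <- group_stats(d)
  expect_equal(gs$mean[gs$category == 1], 0.2)
  expect_equal(gs$se[gs$category == 1], 0.1)
  expect_equal(gs$n[gs$category == 1], 2L)
  # singleton category: SE undefined, reported missing
  expect_true(is.na(gs$se[gs$category == 3]))

  # split-then-average oracle on random groupings
  set.seed(41)
  d2 <- tibble::tibble(score = rnorm(60),
                       intention = sample(1:4, 60, replace = TRUE))
  gs2 <- group_stats(d2)
  for (k in unique(d2$intention)) {
    s <- d2$score[d2$intention == k]
    expect_equal(gs2$mean[gs2$category == k], mean(s))
    if (length(s) > 1) {
      expect_equal(gs2$se[gs2$category == k], sd(s) / sqrt(length(s)))
    }
  }
})

test_that("dummy regression equals group-mean contrasts (one-way ANOVA identity)", {
  # balanced two-group toy data: exact OLS identities
  d <- tibble::tibble(score = c(0.1, 0.2, 0.5, 0.8),
                      intention = c(1, 1, 2, 2))
  reg <- dummy_regression(d)
  td <- tidy(reg)
  expect_equal(td$estimate[td$term == "intercept"], 0.15)
  expect_equal(td$estimate[td$term == "category_2"], 0.65 - 0.15)

  # on arbitrary data every dummy coefficient is a group-mean contrast
  set.seed(51)
  d2 <- tibble::tibble(score = rnorm(120),
                       intention = sample(1:4, 120, replace = TRUE))
  reg2 <- dummy_regression(d2)
  td2 <- tidy(reg2)
  gm <- tapply(d2$score, d2$intention, mean)
  expect_equal(td2$estimate[td2$term == "intercept"], unname(gm["1"]))
  for (k in 2:4) {
    expect_equal(td2$estimate[td2$term == paste0("category_", k)],
                 unname(gm[as.character(k)] - gm["1"]))
  }

  # degrees of freedom at n = 105 with four categories: F(3, 101)
  set.seed(52)
  d3 <- tibble::tibble(score = rnorm(105),
                       intention = rep(1:4, c(50, 36, 18, 1)))
  gl <- glance(dummy_regression(d3))
  expect_equal(gl$df_model, 3L)
  expect_equal(gl$df_residual, 101L)

  expect_error(dummy_regression(tibble::tibble(score = 1:3,
                                               intention = c(1, 1, 1))),
               "two categories")
  expect_error(dummy_regression(d, reference = 3), "reference")
})

test_that("model intention tracks generated empirical intention end to end", {
  f <- trained_f10v()
  sp <- run_single_pass(f$fit$weights, f$patterns, clamp = 0.5)
  sc <- intention_scores(sp)
  sc$intention <- f$survey$intention
  reg <- dummy_regression(sc)
  gl <- glance(reg)
  expect_lt(gl$p_value, 0.05) # significant positive trend at n = 105
  td <- tidy(reg)
  expect_gt(td$estimate[td$term == "category_3"],
            td$estimate[td$term == "category_2"])
})
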