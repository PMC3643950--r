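test_that("pattern error sums visible-unit discrepancies over the error window", {
  nb <- 14
  topo <- make_topology(nb, 10)
  # trajectory whose visible activations equal the target at cycles 7-9
  target <- rep(c(1, 0), each = nb)
  traj <- matrix(0.5, 9, topo$n_units)
  traj[7:9, topo$visible] <- matrix(target, 3, 2 * nb, byrow = TRUE)
  expect_equal(pattern_error(traj, target, visible = topo$visible), 0)

  # all visible at 0.5 against binary targets: 3 cycles x 28 units x 0.25
  traj2 <- matrix(0.5, 9, topo$n_units)
  expect_equal(pattern_error(traj2, target, visible = topo$visible), 21)

  expect_error(pattern_error(traj2, target, error_cycles = 8:10,
                             visible = topo$visible), "trajectory length")
})

test_that("pattern error matches a brute-force summation oracle", {
  set.seed(77)
  topo <- small_topology()
  traj <- matrix(runif(9 * topo$n_units), 9)
  target <- rbinom(6, 1, 0.5)
  got <- pattern_error(traj, target, error_cycles = c(3, 7),
                       visible = topo$visible)
  oracle <- 0
  for (t in c(3, 7)) {
    for (j in seq_along(topo$visible)) {
      oracle <- oracle + (traj[t, topo$visible[j]] - target[j])^2
    }
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  ce <- pattern_error(traj, target, error_cycles = c(3, 7),
                      visible = topo$visible, measure = "cross-entropy")
  oracle_ce <- 0
  for (t in c(3, 7)) {
    for (j in seq_along(topo$visible)) {
      a <- traj[t, topo$visible[j]]
      y <- target[j]
      oracle_ce <- oracle_ce - (y * log(a) + (1 - y) * log(1 - a))
    }
  }
  expect_equal(ce, oracle_ce, tolerance = 1e-12)
})

test_that("backprop-through-settling matches central finite differences", {
  topo <- small_topology()
  w <- init_weights(topo, seed = 7, scale = 0.1)
  w$bias <- rnorm(topo$n_units, sd = 0.05)
  pats <- pattern_matrix(bernoulli_patterns(4, p = 0.5, seed = 2,
                                            n_beliefs = 3))
  for (kappa in c(0, 0.1)) {
    g <- network_gradient(w, pats, clamp = 0.5, kappa = kappa, gain = 1)
    total_err <- function(wt) {
      intentnet:::forward_chain(wt, pats, 0.5, 9, 7:9, kappa, 0.5, 1,
                                1e-6)$error
    }
    h <- 1e-5
    for (idx in which(topo$mask & !topo$fixed)) {
      wp <- w; wp$W[idx] <- wp$W[idx] + h
      wm <- w; wm$W[idx] <- wm$W[idx] - h
      fd <- (total_err(wp) - total_err(wm)) / (2 * h)
      expect_equal(g$grad_W[idx], fd, tolerance = 1e-4)
    }
    for (idx in seq_len(topo$n_units)) {
      wp <- w; wp$bias[idx] <- wp$bias[idx] + h
      wm <- w; wm$bias[idx] <- wm$bias[idx] - h
      fd <- (total_err(wp) - total_err(wm)) / (2 * h)
      expect_equal(g$grad_b[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("gradient is structurally zero on fixed and absent connections", {
  topo <- small_topology()
  w <- small_weights(seed = 8)
  pats <- pattern_matrix(bernoulli_patterns(5, p = 0.4, seed = 3,
                                            n_beliefs = 3))
  g <- network_gradient(w, pats)
  expect_true(all(g$grad_W[topo$fixed] == 0))
  expect_true(all(g$grad_W[!topo$mask] == 0))
})

test_that("without carry-over the batch gradient ignores pattern order", {
  topo <- small_topology()
  w <- small_weights(seed = 8)
  pats <- pattern_matrix(bernoulli_patterns(6, p = 0.4, seed = 4,
                                            n_beliefs = 3))
  g1 <- network_gradient(w, pats, kappa = 0)
  g2 <- network_gradient(w, pats[c(4, 2, 6, 1, 5, 3), ], kappa = 0)
  expect_equal(g1$grad_W, g2$grad_W, tolerance = 1e-12)
  expect_equal(g1$grad_b, g2$grad_b, tolerance = 1e-12)

  # with carry-over the order matters
  g3 <- network_gradient(w, pats, kappa = 0.3)
  g4 <- network_gradient(w, pats[c(4, 2, 6, 1, 5, 3), ], kappa = 0.3)
  expect_false(isTRUE(all.equal(g3$grad_W, g4$grad_W, tolerance = 1e-12)))
})

test_that("training preserves structure and responds to the learning rate", {
  topo <- small_topology()
  w0 <- small_weights(seed = 9)
  pats <- pattern_matrix(bernoulli_patterns(4, p = 0.3, seed = 5,
                                            n_beliefs = 3))

  # zero learning rate: nothing moves
  fit0 <- train_weights(w0, pats, n_epochs = 5, learning_rate = 0)
  expect_identical(fit0$weights$W, w0$W)
  expect_identical(fit0$weights$bias, w0$bias)

  fit <- train_weights(w0, pats, n_epochs = 40)
  # fixed inter-valence links untouched, masked entries still zero
  expect_true(all(fit$weights$W[topo$fixed] == -0.2))
  expect_true(all(fit$weights$W[!topo$mask] == 0))
  # batch error non-increasing over the early epochs at the default step
  expect_true(all(diff(fit$trace$error[1:20]) <= 1e-9))
  expect_equal(nrow(fit$trace), 40)

  # determinism: identical starting point and data give identical fits
  fit2 <- train_weights(w0, pats, n_epochs = 40)
  expect_identical(fit$weights$W, fit2$weights$W)

  expect_error(train_weights(w0, pats, momentum = 1), "momentum")
  expect_error(train_weights(w0, pats, error_cycles = 10:11), "error_cycles")
})

test_that("training on a not-intend-leaning context learns that bias", {
  # after training on P25-style patterns, a null input under training clamp
  # activates the not-intend bank more than the intend bank
  fit <- trained_p25()
  topo <- fit$weights$topology
  traj <- settle(fit$weights, rep(0, 28), clamp = 0.5)
  final <- traj[9, ]
  expect_gt(mean(final[topo$notintend]), mean(final[topo$intend]))
})

test_that("tidy and glance summarize a fit", {
  w0 <- small_weights(seed = 9)
  pats <- pattern_matrix(bernoulli_patterns(4, p = 0.3, seed = 5,
                                            n_beliefs = 3))
  fit <- train_weights(w0, pats, n_epochs = 8)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  gl <- glance(fit)
  expect_equal(gl$n_epochs, 8)
  expect_equal(gl$final_error, td$error[8])
  expect_s3_class(autoplot(fit), "ggplot")
})
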