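test_that("utility is money minus envy-only norm-violation penalty", {
  # rejection always yields exactly zero, whatever the norm
  expect_identical(ft_utility(7, 15, 0.9, FALSE), 0)
  expect_identical(ft_utility(0, 0, 0, FALSE), 0)
  # no penalty when the offer meets or exceeds the norm
  expect_equal(ft_utility(6, 4, 0.9, TRUE), 6)
  # shortfall penalized in proportion to alpha
  expect_equal(ft_utility(4, 8, 0.5, TRUE), 2)
  expect_equal(ft_utility(c(4, 6), c(8, 4), 0.5, c(TRUE, TRUE)), c(2, 6))
  expect_error(ft_utility(5, -1, 0.5, TRUE), "non-negative")
  expect_error(ft_utility(5, 5, 1.5, TRUE), "alpha")
  # hypothetical offers below zero are valued, not rejected: the mental
  # simulation's reject branch has no floor
  expect_equal(ft_utility(-1, 5, 0.5, TRUE), -4)
})

test_that("norm update is a Rescorla-Wagner convex step toward the offer", {
  expect_equal(update_norm(8, 4, 0), 8)
  expect_equal(update_norm(8, 4, 1), 4)
  expect_equal(update_norm(8, 4, 0.25), 7)
  expect_error(update_norm(8, 4, 1.2), "eps")
  # property: the result always lies between the previous norm and the offer
  set.seed(10)
  for (i in 1:200) {
    f <- runif(1, 0, 20); s <- runif(1, 0, 9); e <- runif(1)
    out <- update_norm(f, s, e)
    expect_true(out >= min(f, s) - 1e-12 && out <= max(f, s) + 1e-12)
  }
})

test_that("norm trajectory stays within the convex hull of f0 and the offers", {
  set.seed(11)
  for (i in 1:50) {
    offers <- sample(1:9, 40, TRUE)
    f0 <- runif(1, 0, 20); eps <- runif(1)
    nt <- norm_trajectory(offers, f0, eps)
    for (t in seq_along(offers)) {
      hull <- range(c(f0, offers[seq_len(t)]))
      expect_true(nt$norm_used[t] >= hull[1] - 1e-10 &&
                    nt$norm_used[t] <= hull[2] + 1e-10)
    }
    expect_equal(nt$npe[1], offers[1] - f0)
  }
  # "after" timing values trial i against the pre-update norm
  nt_b <- norm_trajectory(c(3, 7), 10, 0.5, "before")
  nt_a <- norm_trajectory(c(3, 7), 10, 0.5, "after")
  expect_equal(nt_a$norm_used, c(10, 6.5))
  expect_equal(nt_b$norm_used, c(6.5, 6.75))
})

test_that("hypothetical offers follow the expected-influence rule", {
  expect_equal(hypothetical_next_offer(5, 0, 1.5), 6.5)
  expect_equal(hypothetical_next_offer(2, 1, 2), 1)   # $1 floor on accept
  expect_equal(hypothetical_next_offer(5, 1, -1), 6)  # negative influence
  expect_equal(hypothetical_next_offer(9, 0, 2), 11)  # no ceiling on reject
})

test_that("simulated future actions are greedy with ties broken to reject", {
  expect_identical(simulated_action(6, 3, 1), 1L)
  expect_identical(simulated_action(2, 8, 1), 0L)  # 2 - 6 < 0
  expect_identical(simulated_action(0, 5, 0.3), 0L) # tie at exactly 0
})

test_that("rollout value matches the brute-force path enumerator", {
  # zero horizon is just the current utility
  p0 <- ft_params(8, 0.76, 8.21, 0.24, 1.33, n_steps = 0)
  expect_equal(rollout_value(1L, 5, 8, p0)$value,
               ft_utility(5, 8, 0.76, TRUE))
  expect_equal(rollout_value(0L, 5, 8, p0)$value, 0)

  # the frozen example from the oracle
  p2 <- ft_params(8, 0.76, 8.21, 0.24, 1.33, n_steps = 2)
  rv <- rollout_value(1L, 5, 8, p2)
  expect_equal(rv$value, oracle_rollout_value(1L, 5, 8, p2), tolerance = 1e-12)
  expect_equal(rv$value, rv$cv + rv$fv)
  expect_equal(nrow(rv$path), 2)

  # property: oracle equivalence over random states at all horizons
  set.seed(12)
  for (i in 1:200) {
    p <- random_ft_params()
    offer <- sample(1:9, 1)
    norm <- runif(1, 0, 20)
    a <- sample(0:1, 1)
    expect_lt(abs(rollout_value(a, offer, norm, p)$value -
                    oracle_rollout_value(a, offer, norm, p)), 1e-10)
  }
})

test_that("hypothetical accept-branch offers never fall below $1", {
  set.seed(13)
  for (i in 1:100) {
    p <- random_ft_params(n_steps = 4)
    av <- action_values(sample(1:9, 1), runif(1, 0, 20), p)
    # the floor applies wherever a simulated acceptance generated the next
    # offer; steps following a simulated rejection have no floor
    for (a0 in c(0L, 1L)) {
      branch <- av$paths[[a0 + 1L]]
      prev_a <- c(a0, branch$action[-nrow(branch)])
      after_accept <- which(prev_a == 1L)
      expect_true(all(branch$offer[after_accept] >= 1))
    }
  }
})

test_that("zero expected influence collapses every horizon to the myopic Q", {
  set.seed(14)
  for (i in 1:100) {
    offer <- sample(1:9, 1); norm <- runif(1, 0, 20)
    beta <- runif(1, 0, 20); alpha <- runif(1); f0 <- runif(1, 0, 20)
    eps <- runif(1)
    q0 <- action_values(offer, norm,
                        ft_params(beta, alpha, f0, eps, 0, n_steps = 0))$Q
    for (h in 1:4) {
      qh <- action_values(offer, norm,
                          ft_params(beta, alpha, f0, eps, 0, n_steps = h))$Q
      expect_lt(abs(qh - q0), 1e-10)
    }
  }
})

test_that("softmax choice rule is symmetric, bounded and monotone", {
  # beta = 0 gives exactly 0.5 whatever the values
  av0 <- action_values(3, 9, ft_params(0, 0.9, 9, 0.3, 1.2))
  expect_equal(av0$p_accept, 0.5)
  set.seed(15)
  for (i in 1:100) {
    avi <- action_values(sample(1:9, 1), runif(1, 0, 20), random_ft_params())
    expect_true(avi$p_accept >= 0 && avi$p_accept <= 1)
    # strictly interior wherever the logistic has not saturated in doubles
    if (abs(avi$Q) * 20 < 36)
      expect_true(avi$p_accept > 0 && avi$p_accept < 1)
  }
  # strict monotonicity in Q at fixed beta, via the likelihood components
  q <- seq(-5, 5, length.out = 21)
  expect_true(all(diff(plogis(3 * q)) > 0))
})

test_that("session likelihood scores only the fit window but learns on all trials", {
  set.seed(16)
  s <- random_session(40)
  # beta = 0: every choice has probability 1/2
  p_flat <- ft_params(0, 0.5, 10, 0.3, 1)
  expect_equal(session_loglik(s, p_flat), 30 * log(2))
  expect_equal(session_loglik(s, p_flat, window = fit_window(40)),
               30 * log(2))
  expect_length(fit_window(40), 30)
  expect_length(fit_window(30), 20)
  expect_error(fit_window(10), "empty")

  # norm state advances through excluded trials: scoring window {6..35}
  # must differ from a likelihood that restarts the norm at trial 6
  p <- ft_params(4, 0.8, 15, 0.4, 1)
  nll_full <- session_loglik(s, p)
  s_trunc <- session_data("t", s$condition, s$offers[6:35], s$choices[6:35])
  nll_restart <- session_loglik(s_trunc, p, window = 1:30)
  expect_false(isTRUE(all.equal(nll_full, nll_restart)))
})

test_that("scalar and trial-vectorized valuation routes agree", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_session(30)
    p <- random_ft_params()
    sv <- session_valuations(s, p)
    nll_scalar <- -sum(log(pmax(
      ifelse(s$choices == 1, sv$p_accept, 1 - sv$p_accept), 1e-12
    ))[fit_window(30)])
    expect_equal(session_loglik(s, p), nll_scalar, tolerance = 1e-10)
    expect_equal(sv$tv_chosen, sv$cv_chosen + sv$fv_chosen, tolerance = 1e-12)
  }
})

test_that("near-deterministic agents are almost perfectly explained by truth", {
  # choices generated greedily from the params (accept iff Q > 0), scored
  # at the same params with beta at the upper bound
  p <- ft_params(20, 0.76, 8.21, 0.24, 1.33)
  set.seed(18)
  cfg <- env_config("controllable", 40)
  pol_env <- new.env()
  pol_env$f <- p$f0
  greedy <- function(offer, trial) {
    pol_env$f <- update_norm(pol_env$f, offer, p$eps)
    av <- action_values(offer, pol_env$f, p)
    as.integer(av$Q > 0)
  }
  s <- run_session(greedy, cfg, seed = 19)
  expect_lt(session_loglik(s, p), 1.5)
  expect_equal(prediction_accuracy(s, p), 1.0)
})

test_that("value regressors decompose and z-score correctly", {
  set.seed(20)
  s <- random_session(40)
  p <- ft_params(6, 0.7, 9, 0.3, 1.2, n_steps = 2)
  reg <- export_value_regressors(s, p)
  expect_equal(nrow(reg), 40)
  expect_lt(abs(mean(reg$tv)), 1e-10)
  expect_equal(sd(reg$tv), 1, tolerance = 1e-10)
  expect_equal(reg$tv_raw, reg$cv + reg$fv, tolerance = 1e-12)
  expect_false(any(reg$tv_constant))

  # zero horizon: no future value, tv is the current value before scaling
  p0 <- ft_params(6, 0.7, 9, 0.3, 1.2, n_steps = 0)
  reg0 <- export_value_regressors(s, p0)
  expect_true(all(reg0$fv == 0))
  expect_equal(reg0$tv_raw, reg0$cv)

  # an all-reject session has constant zero chosen value
  s_flat <- session_data("f", "controllable", rep(5, 40), rep(0, 40))
  expect_warning(regf <- export_value_regressors(s_flat, p0),
                 "zero-variance")
  expect_true(all(regf$tv_constant))
})
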