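test_that("sigmoid parameter transform is a bijection onto the bounds", {
  mid <- transform_params(rep(0, 5))
  expect_equal(mid$beta, 10)
  expect_equal(mid$alpha, 0.5)
  expect_equal(mid$f0, 10)
  expect_equal(mid$eps, 0.5)
  expect_equal(mid$delta, 0)

  set.seed(30)
  for (i in 1:50) {
    x <- rnorm(5, 0, 3)
    p <- transform_params(x)
    expect_true(all(abs(untransform_params(p) - x) < 1e-8))
    expect_true(p$beta >= 0 && p$beta <= 20 && abs(p$delta) <= 2)
  }
  # logistic saturation near the upper bound
  expect_lt(abs(transform_params(c(0, 0, 0, 0, 36))$delta - 2), 1e-9)
  # untransform clips exact-bound parameters to finite values
  at_bound <- ft_params(beta = 0, alpha = 1, f0 = 20, eps = 0, delta = 2)
  expect_true(all(is.finite(untransform_params(at_bound))))
  expect_true(all(abs(untransform_params(at_bound)) <= 36))
})

test_that("information criterion penalizes parameters at the stated rate", {
  nll <- 30 * log(2)
  expect_equal(dic_score(nll, 5, 30), 2 * nll + 5 * (log(30) - log(2 * pi)))
  expect_equal(dic_score(nll, 0, 30), 2 * nll)
  expect_gt(dic_score(nll, 6, 30), dic_score(nll, 5, 30))
  expect_error(dic_score(nll, 5, 0))
})

test_that("prediction accuracy thresholds the acceptance probability at 0.5", {
  # deterministic self-prediction
  p <- ft_params(20, 0.76, 8.21, 0.24, 1.33)
  cfg <- env_config("controllable", 40)
  env <- new.env(); env$f <- p$f0
  greedy <- function(offer, trial) {
    env$f <- update_norm(env$f, offer, p$eps)
    as.integer(action_values(offer, env$f, p)$Q > 0)
  }
  s <- run_session(greedy, cfg, seed = 31)
  expect_equal(prediction_accuracy(s, p), 1.0)
  expect_length(fit_window(length(s$offers)), 30)

  # coin-flip choices are predicted at chance by any parameters
  set.seed(32)
  offers <- sample(2:8, 400, TRUE)
  s_coin <- session_data("c", "uncontrollable_gaussian", offers,
                         sample(0:1, 400, TRUE))
  acc <- prediction_accuracy(s_coin, ft_params(8, 0.7, 9, 0.3, 1),
                             window = fit_window(400))
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("fitting recovers parameters from a long near-noiseless session", {
  # stress fixture: one agent, high beta, long session
  truth <- ft_params(10, 0.76, 8.21, 0.24, 1.33)
  pol <- ft_policy(truth)
  s <- run_session(pol, env_config("controllable", 2000), seed = 33)
  fit <- fit_subject(s, n_steps = 2, config = fit_config(n_restarts = 6))
  expect_lt(abs(fit$params_hat$delta - truth$delta), 0.2)
  expect_equal(fit$n_fit_trials, 1990)
  # the optimum can only beat (or tie) the generating parameters
  expect_lte(fit$neg_loglik, session_loglik(s, truth) + 1e-6)
})

test_that("fit results satisfy their contracts on ordinary sessions", {
  spec <- population_spec(3, env = env_config("controllable", 40))
  cohort <- simulate_cohort(spec, seed = 34)
  f <- fit_subject(cohort$sessions[[1]], 2, fit_config(n_restarts = 8))
  expect_equal(f$n_fit_trials, 30)
  expect_true(f$params_hat$beta >= 0 && f$params_hat$beta <= 20)
  expect_true(abs(f$params_hat$delta) <= 2)
  expect_true(f$accuracy >= 0 && f$accuracy <= 1)
  expect_equal(f$dic, dic_score(f$neg_loglik, 5, 30))
  expect_gte(f$n_restarts_ok, 1)
  # negLL at the generating parameters bounds the optimum from above
  gen <- ft_params(cohort$ledger$beta[1], cohort$ledger$alpha[1],
                   cohort$ledger$f0[1], cohort$ledger$eps[1],
                   cohort$ledger$delta[1])
  expect_lte(f$neg_loglik, session_loglik(cohort$sessions[[1]], gen) + 1e-6)

  # degenerate all-accept session still converges
  s_flat <- session_data("f", "controllable", rep(5, 40), rep(1, 40))
  f_flat <- fit_subject(s_flat, 2, fit_config(n_restarts = 4))
  expect_equal(f_flat$accuracy, 1.0)
})

test_that("horizon comparison produces a complete DIC table with paired tests", {
  spec <- population_spec(4, env = env_config("controllable", 40))
  cohort <- simulate_cohort(spec, seed = 35)
  cmp <- compare_horizons(cohort$sessions, horizons = c(0, 2),
                          config = fit_config(n_restarts = 5))
  expect_equal(nrow(cmp$dic), 4)
  expect_true(all(is.finite(as.matrix(cmp$dic[c("h0", "h2")]))))
  expect_named(cmp$mean_dic, c("h0", "h2"))
  expect_equal(nrow(cmp$t_tests), 1)
  expect_equal(cmp$t_tests$df, 3)
})
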