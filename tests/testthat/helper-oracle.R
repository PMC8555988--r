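# Independent brute-force oracle for the forward rollout: a recursive
# enumeration of the deterministic greedy path, coded without reference to
# the package's iterative implementation.

oracle_rollout_value <- function(current_action, offer, norm, params) {
  u <- function(s, a) {
    if (a == 1) s - params$alpha * max(norm - s, 0) else 0
  }
  next_offer <- function(s, a) {
    if (a == 0) s + params$delta else max(s - params$delta, 1)
  }
  recurse <- function(s_prev, a_prev, depth) {
    if (depth > params$n_steps) return(0)
    s <- next_offer(s_prev, a_prev)
    a <- if (s - params$alpha * max(norm - s, 0) > 0) 1L else 0L
    params$gamma^depth * u(s, a) + recurse(s, a, depth + 1L)
  }
  u(offer, current_action) + recurse(offer, current_action, 1L)
}

oracle_Q <- function(offer, norm, params) {
  oracle_rollout_value(1L, offer, norm, params) -
    oracle_rollout_value(0L, offer, norm, params)
}

# Random interior parameter set for property tests
random_ft_params <- function(n_steps = sample(0:4, 1)) {
  ft_params(beta = runif(1, 0, 20), alpha = runif(1, 0, 1),
            f0 = runif(1, 0, 20), eps = runif(1, 0, 1),
            delta = runif(1, -2, 2), n_steps = n_steps)
}

random_session <- function(n_trials = 40L, condition = "controllable") {
  lim <- if (condition == "uncontrollable_gaussian") c(2, 8) else c(1, 9)
  # random-walk offers stay within the controllable step-size invariant
  offers <- numeric(n_trials)
  offers[1] <- 5
  for (t in seq_len(n_trials - 1))
    offers[t + 1] <- min(max(offers[t] + sample(-2:2, 1), lim[1]), lim[2])
  session_data("rand", condition, offers, sample(0:1, n_trials, TRUE))
}
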