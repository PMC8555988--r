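# Norm-adaptation utility, Rescorla-Wagner norm learning, deterministic
# greedy forward rollout and softmax choice rule for planning horizons 0-4.

FT_BOUNDS <- list(beta = c(0, 20), alpha = c(0, 1), f0 = c(0, 20),
                  eps = c(0, 1), delta = c(-2, 2))

#' Forward-thinking model parameters
#'
#' The five free parameters of the responder model plus the fixed temporal
#' discount and the planning horizon:
#' \describe{
#'   \item{beta}{softmax inverse temperature, in `[0, 20]`.}
#'   \item{alpha}{sensitivity to norm violation, in `[0, 1]`.}
#'   \item{f0}{initial internal norm, dollars, in `[0, 20]`.}
#'   \item{eps}{norm adaptation (learning) rate, in `[0, 1]`.}
#'   \item{delta}{expected influence: the dollar change per trial the agent
#'     believes a rejection (+) or acceptance (-) induces in future offers
#'     during mental simulation, in `[-2, 2]`.}
#'   \item{gamma}{temporal discount, fixed at 0.8.}
#'   \item{n_steps}{planning horizon, 0 (no forward thinking) to 4.}
#' }
#'
#' @param beta,alpha,f0,eps,delta free parameters (see Details).
#' @param gamma temporal discount factor.
#' @param n_steps planning horizon in `{0, 1, 2, 3, 4}`.
#' @return An `ft_params` object.
#' @export
ft_params <- function(beta, alpha, f0, eps, delta, gamma = 0.8, n_steps = 2L) {
  p <- list(beta = beta, alpha = alpha, f0 = f0, eps = eps, delta = delta,
            gamma = gamma, n_steps = as.integer(n_steps))
  for (nm in names(FT_BOUNDS)) {
    b <- FT_BOUNDS[[nm]]
    if (!is.finite(p[[nm]]) || p[[nm]] < b[1] || p[[nm]] > b[2])
      stop(nm, " = ", p[[nm]], " outside [", b[1], ", ", b[2], "]")
  }
  if (!p$n_steps %in% 0:4) stop("n_steps must be in {0, ..., 4}")
  structure(p, class = "ft_params")
}

#' @export
print.ft_params <- function(x, ...) {
  cat(sprintf(
    "<ft_params> beta=%.3g alpha=%.3g f0=%.3g eps=%.3g delta=%.3g (gamma=%.2g, %d-step)\n",
    x$beta, x$alpha, x$f0, x$eps, x$delta, x$gamma, x$n_steps))
  invisible(x)
}

#' Subjective utility of one trial outcome
#'
#' Accepting an offer `s` against internal norm `f` yields
#' `s - alpha * max(f - s, 0)`: the money received minus an aversion penalty
#' proportional to the shortfall of the offer below the norm (envy only; no
#' penalty for offers above the norm). Rejecting yields exactly 0 -- the
#' known consequence of rejection, so no norm aversion applies.
#'
#' Observed offers are non-negative, but hypothetical offers reached during
#' mental simulation with a negative expected influence may dip below zero
#' (the reject branch has no floor), so only the norm and alpha domains are
#' enforced here.
#'
#' @param offer offer in dollars.
#' @param norm internal norm in dollars (non-negative).
#' @param alpha sensitivity to norm violation in `[0, 1]`.
#' @param accepted logical (or 0/1): was the offer accepted?
#' @return Utility (vectorized over `offer`/`norm`/`accepted`).
#' @export
ft_utility <- function(offer, norm, alpha, accepted) {
  if (any(norm < 0) || alpha < 0 || alpha > 1)
    stop("norm must be non-negative and alpha in [0, 1]")
  ifelse(as.logical(accepted), offer - alpha * pmax(norm - offer, 0), 0)
}

#' Rescorla-Wagner update of the internal norm
#'
#' `f <- f + eps * (s - f)`: the norm moves toward the observed offer by a
#' fraction `eps` of the norm prediction error, so the result always lies
#' between the previous norm and the offer.
#'
#' @param prev_norm previous norm, dollars.
#' @param offer observed offer, dollars.
#' @param eps adaptation rate in `[0, 1]`.
#' @return Updated norm (vectorized).
#' @export
update_norm <- function(prev_norm, offer, eps) {
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  prev_norm + eps * (offer - prev_norm)
}

#' Hypothetical next offer during mental simulation
#'
#' A simulated rejection raises the imagined next offer by `delta` with no
#' ceiling (the agent is not assumed to know the task's upper bound); a
#' simulated acceptance lowers it by `delta`, floored at $1 (an offer of $0
#' would make accept and reject indistinguishable).
#'
#' @param offer current (hypothetical) offer, dollars.
#' @param action 0 = reject, 1 = accept.
#' @param delta expected influence, dollars.
#' @return Hypothetical next offer (vectorized over `offer`/`action`).
#' @export
hypothetical_next_offer <- function(offer, action, delta) {
  ifelse(action == 0, offer + delta, pmax(offer - delta, 1))
}

#' Deterministic simulated action at a hypothetical future offer
#'
#' Accept iff the acceptance utility is strictly positive (a tie at exactly
#' zero is a reject) -- greedy one-step lookahead, not a softmax draw.
#'
#' @inheritParams ft_utility
#' @return 0 or 1 (vectorized).
#' @export
simulated_action <- function(offer, norm, alpha) {
  as.integer(ft_utility(offer, norm, alpha, TRUE) > 0)
}

#' Rollout value of a current action
#'
#' The value of taking `current_action` at `offer` is the current utility
#' plus the discounted sum of utilities along a single deterministic greedy
#' path of `n_steps` mentally simulated future trials: each hypothetical
#' offer follows the expected-influence rule (driven first by the current
#' action, then by the simulated actions), each simulated action is the
#' greedy accept/reject at that offer, and all utilities are evaluated
#' against the trial's norm (held frozen during the rollout by default).
#'
#' @param current_action 0 = reject, 1 = accept.
#' @param offer current offer, dollars.
#' @param norm the trial's internal norm, dollars.
#' @param params an [ft_params()].
#' @param rollout_norm_update update the norm with each hypothetical offer
#'   inside the rollout (sensitivity alternative)? Default `FALSE`: the norm
#'   is frozen at the trial's value.
#' @return List with `value` (utility units), `cv` (depth-0 term), `fv`
#'   (discounted future sum), and `path`, a data.frame of the simulated
#'   depth-1..n offers, actions, and discounted utilities.
#' @export
rollout_value <- function(current_action, offer, norm, params,
                          rollout_norm_update = FALSE) {
  if (!params$n_steps %in% 0:4) stop("n_steps must be in {0, ..., 4}")
  cv <- ft_utility(offer, norm, params$alpha, current_action)
  fv <- 0
  s <- offer
  a <- current_action
  f <- norm
  path <- if (params$n_steps > 0)
    data.frame(depth = seq_len(params$n_steps), offer = NA_real_,
               action = NA_integer_, utility = NA_real_)
  else
    data.frame(depth = integer(), offer = numeric(),
               action = integer(), utility = numeric())
  for (j in seq_len(params$n_steps)) {
    s <- hypothetical_next_offer(s, a, params$delta)
    if (rollout_norm_update) f <- update_norm(f, s, params$eps)
    a <- simulated_action(s, f, params$alpha)
    u <- ft_utility(s, f, params$alpha, a)
    fv <- fv + params$gamma^j * u
    path$offer[j] <- s
    path$action[j] <- a
    path$utility[j] <- u
  }
  list(value = cv + fv, cv = cv, fv = fv, path = path)
}

#' Action values, choice probability and value decomposition for one trial
#'
#' Computes the rollout values of accepting and rejecting the current offer,
#' their difference `Q = v(accept) - v(reject)`, and the softmax acceptance
#' probability `1 / (1 + exp(-beta * Q))` (computed overflow-safely).
#'
#' @inheritParams rollout_value
#' @return A `trial_valuation` list: `norm_used`, `v_accept`, `v_reject`,
#'   `Q`, `p_accept`, per-action `cv`/`fv`/`tv`, and the two rollout paths.
#' @export
action_values <- function(offer, norm, params, rollout_norm_update = FALSE) {
  acc <- rollout_value(1L, offer, norm, params, rollout_norm_update)
  rej <- rollout_value(0L, offer, norm, params, rollout_norm_update)
  q <- acc$value - rej$value
  p <- stats::plogis(params$beta * q)
  if (!is.finite(q) || !is.finite(p))
    stop("non-finite valuation at offer=", offer, ", norm=", norm)
  structure(
    list(norm_used = norm, v_accept = acc$value, v_reject = rej$value,
         Q = q, p_accept = p,
         cv = c(reject = rej$cv, accept = acc$cv),
         fv = c(reject = rej$fv, accept = acc$fv),
         tv = c(reject = rej$value, accept = acc$value),
         paths = list(reject = rej$path, accept = acc$path)),
    class = "trial_valuation")
}

#' Internal norm trajectory over a session
#'
#' With update-before-valuation timing (the default), the norm entering
#' trial i's utilities has already been updated with trial i's offer; with
#' `"after"` timing trial i is valued against the previous norm and updated
#' afterwards. The norm prediction error is always `s_i - f_{i-1}`.
#'
#' @param offers integer offer vector.
#' @param f0 initial norm.
#' @param eps adaptation rate.
#' @param norm_timing `"before"` (update with the current offer before
#'   valuation) or `"after"`.
#' @return List with `norm_used` (norm entering each trial's utilities) and
#'   `npe` (per-trial norm prediction error), both length of `offers`.
#' @export
norm_trajectory <- function(offers, f0, eps, norm_timing = c("before", "after")) {
  norm_timing <- match.arg(norm_timing)
  n <- length(offers)
  # f_i = (1 - eps) * f_{i-1} + eps * s_i, vectorized recursive filter
  f <- as.numeric(stats::filter(eps * offers, 1 - eps,
                                method = "recursive", init = f0))
  f_prev <- c(f0, f[-n])
  list(norm_used = if (norm_timing == "before") f else f_prev,
       npe = offers - f_prev)
}

# Trial-vectorized Q values for a whole session: the fitting hot path.
# Identical mathematics to action_values(), but every depth of the rollout
# is a vector operation across trials. Norm frozen at the trial norm.
session_Q <- function(offers, norm_used, params) {
  alpha <- params$alpha
  delta <- params$delta
  gam <- params$gamma
  u_acc <- function(s, f) s - alpha * pmax(f - s, 0)
  v <- list()
  for (a0 in c(0L, 1L)) {
    cv <- if (a0 == 1L) u_acc(offers, norm_used) else rep(0, length(offers))
    fv <- 0
    s <- offers
    a <- rep(a0, length(offers))
    for (j in seq_len(params$n_steps)) {
      s <- ifelse(a == 0L, s + delta, pmax(s - delta, 1))
      ua <- u_acc(s, norm_used)
      a <- as.integer(ua > 0)
      fv <- fv + gam^j * ifelse(a == 1L, ua, 0)
    }
    v[[a0 + 1L]] <- cv + fv
  }
  v[[2L]] - v[[1L]]
}

#' Default fit window: drop the first and last five trials
#'
#' Initial trials are excluded because subjects are still learning the
#' action-offer contingency; final trials because end-of-block incentives
#' change (less room to raise offers). A 40-trial block leaves 30 fitted
#' trials; a 30-trial block leaves 20.
#'
#' @param n_trials session length.
#' @param exclude_first,exclude_last trials dropped at each end.
#' @return Integer vector of fitted trial indices.
#' @export
fit_window <- function(n_trials, exclude_first = 5L, exclude_last = 5L) {
  if (exclude_first + exclude_last >= n_trials) stop("empty fit window")
  seq.int(exclude_first + 1L, n_trials - exclude_last)
}

#' Negative log-likelihood of a session under the model
#'
#' Iterates all trials in order, maintaining the norm state across every
#' trial (including excluded ones), but accumulates `-log P(observed
#' choice)` only over the fit window. Probabilities are floored at 1e-12
#' before the log, so the value is always finite.
#'
#' @param session a [session_data()].
#' @param params an [ft_params()].
#' @param window integer trial indices to score (default: [fit_window()]).
#' @param norm_timing see [norm_trajectory()].
#' @return Scalar negative log-likelihood.
#' @export
session_loglik <- function(session, params, window = NULL,
                           norm_timing = "before") {
  if (is.null(window)) window <- fit_window(length(session$offers))
  if (length(window) < 1L) stop("empty fit window")
  stopifnot(all(window >= 1), all(window <= length(session$offers)))
  nt <- norm_trajectory(session$offers, params$f0, params$eps, norm_timing)
  q <- session_Q(session$offers, nt$norm_used, params)
  p <- stats::plogis(params$beta * q)
  p_obs <- ifelse(session$choices == 1L, p, 1 - p)[window]
  -sum(log(pmax(p_obs, 1e-12)))
}

#' Per-trial valuations for a whole session
#'
#' Runs [action_values()] at every trial with the evolving norm, returning
#' one row per trial with the norm, norm prediction error, Q, acceptance
#' probability, and the chosen action's current/future/total value.
#'
#' @inheritParams session_loglik
#' @return A tibble with one row per trial.
#' @export
session_valuations <- function(session, params, norm_timing = "before") {
  nt <- norm_trajectory(session$offers, params$f0, params$eps, norm_timing)
  n <- length(session$offers)
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    av <- action_values(session$offers[t], nt$norm_used[t], params)
    ch <- session$choices[t] + 1L  # 1 = reject, 2 = accept
    rows[[t]] <- tibble::tibble(
      trial = t, offer = session$offers[t], choice = session$choices[t],
      norm = nt$norm_used[t], npe = nt$npe[t],
      v_accept = av$v_accept, v_reject = av$v_reject,
      Q = av$Q, p_accept = av$p_accept,
      cv_chosen = av$cv[[ch]], fv_chosen = av$fv[[ch]],
      tv_chosen = av$tv[[ch]])
  }
  do.call(rbind, rows)
}

#' Trial-level value regressors of the chosen action
#'
#' Exports the per-trial total, current and future values of the chosen
#' action (the quantities used as trial-by-trial parametric modulators in
#' model-based neural analyses), with the total value z-scored within the
#' session. If the TV column has zero variance the unnormalized column is
#' returned with `tv_constant = TRUE`.
#'
#' @inheritParams session_loglik
#' @return A tibble: subject_id, trial, tv, cv, fv, npe, norm, plus a
#'   `tv_constant` attribute-like column flag.
#' @export
export_value_regressors <- function(session, params, norm_timing = "before") {
  sv <- session_valuations(session, params, norm_timing)
  tv <- sv$tv_chosen
  s <- stats::sd(tv)
  constant <- !is.finite(s) || s == 0
  if (constant) {
    warning("zero-variance total value; emitting unnormalized column")
    tv_z <- tv
  } else {
    tv_z <- (tv - mean(tv)) / s
  }
  tibble::tibble(
    subject_id = session$subject_id, trial = sv$trial,
    tv = tv_z, cv = sv$cv_chosen, fv = sv$fv_chosen,
    tv_raw = sv$tv_chosen, npe = sv$npe, norm = sv$norm,
    tv_constant = constant)
}
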