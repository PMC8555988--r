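# Populations of forward-thinking agents and full synthetic cohorts with
# the statistical structure the downstream analyses assume.

#' Published group-level parameter moments (2-step model)
#'
#' Mean and SD of the five free parameters estimated from the 2-step model,
#' by sample and condition; the default generating distribution for
#' recovery simulations.
#'
#' @param condition `"controllable"` or `"uncontrollable"`.
#' @param sample `"fmri"` or `"online"`.
#' @return Named list of `c(mean, sd)` pairs for beta, alpha, f0, eps, delta.
#' @export
published_moments <- function(condition = c("controllable", "uncontrollable"),
                              sample = c("fmri", "online")) {
  condition <- match.arg(condition)
  sample <- match.arg(sample)
  m <- list(
    controllable = list(
      fmri   = list(beta = c(8.33, 8.55), alpha = c(0.76, 0.29),
                    f0 = c(8.21, 7.14), eps = c(0.24, 0.24),
                    delta = c(1.33, 0.79)),
      online = list(beta = c(9.77, 8.54), alpha = c(0.74, 0.29),
                    f0 = c(9.01, 7.26), eps = c(0.32, 0.31),
                    delta = c(1.34, 0.84))),
    uncontrollable = list(
      fmri   = list(beta = c(10.38, 8.84), alpha = c(0.79, 0.31),
                    f0 = c(8.84, 6.96), eps = c(0.29, 0.24),
                    delta = c(0.98, 0.62)),
      online = list(beta = c(12.94, 7.66), alpha = c(0.78, 0.23),
                    f0 = c(9.07, 6.31), eps = c(0.24, 0.24),
                    delta = c(0.90, 1.06))))
  m[[condition]][[sample]]
}

#' Specification of a simulated agent population
#'
#' @param n_subjects number of agents (default 48, the laboratory sample
#'   size).
#' @param moments named list of `c(mean, sd)` generating moments per free
#'   parameter; default the laboratory controllable-condition estimates
#'   ([published_moments()]). Each parameter is drawn from a normal truncated
#'   to its model bounds.
#' @param horizon generating planning horizon (default 2).
#' @param gamma temporal discount (fixed 0.8).
#' @param env an [env_config()]; default a 40-trial controllable block.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects = 48L,
                            moments = published_moments("controllable", "fmri"),
                            horizon = 2L,
                            gamma = 0.8,
                            env = env_config("controllable", n_trials = 40L)) {
  stopifnot(n_subjects >= 1,
            setequal(names(moments), names(FT_BOUNDS)))
  for (nm in names(FT_BOUNDS)) {
    b <- FT_BOUNDS[[nm]]
    if (moments[[nm]][1] < b[1] || moments[[nm]][1] > b[2])
      stop("generating mean for ", nm, " outside model bounds")
    if (moments[[nm]][2] < 0) stop("generating SD for ", nm, " negative")
  }
  structure(list(n_subjects = as.integer(n_subjects), moments = moments,
                 horizon = as.integer(horizon), gamma = gamma, env = env),
            class = "population_spec")
}

# Truncated-normal draws by inverse CDF on the truncated interval:
# deterministic under a fixed seed (no rejection loop). sd = 0 collapses to
# the mean.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-6)
    stop("degenerate truncation: < 1e-6 probability mass inside [",
         lo, ", ", hi, "]")
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

# Analytic mean of the truncated normal (test oracle lives with the sampler).
truncnorm_mean <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Sample agent parameters from a population specification
#'
#' Each free parameter is drawn independently from a normal with the
#' specified moments, truncated to the model bounds; gamma and the horizon
#' are fixed at the specification's values.
#'
#' @param spec a [population_spec()].
#' @param seed optional integer seed.
#' @return List of `n_subjects` [ft_params()] objects.
#' @export
sample_params <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(names(FT_BOUNDS), function(nm) {
    b <- FT_BOUNDS[[nm]]
    m <- spec$moments[[nm]]
    rtruncnorm_inv(spec$n_subjects, m[1], m[2], b[1], b[2])
  })
  names(draws) <- names(FT_BOUNDS)
  lapply(seq_len(spec$n_subjects), function(i)
    ft_params(beta = draws$beta[i], alpha = draws$alpha[i],
              f0 = draws$f0[i], eps = draws$eps[i], delta = draws$delta[i],
              gamma = spec$gamma, n_steps = spec$horizon))
}

#' Softmax agent policy for a session
#'
#' Returns a stateful policy closure for [run_session()]: at each trial it
#' updates its internal norm with the presented offer, computes the
#' trial-vectorized action values at its own parameters, and accepts with
#' the softmax probability (a Bernoulli draw from the current RNG stream).
#'
#' @param params an [ft_params()].
#' @param norm_timing see [norm_trajectory()].
#' @return `function(offer, trial) -> 0/1`.
#' @export
ft_policy <- function(params, norm_timing = "before") {
  f <- params$f0
  function(offer, trial) {
    npe_norm <- update_norm(f, offer, params$eps)
    norm_used <- if (norm_timing == "before") npe_norm else f
    f <<- npe_norm
    q <- session_Q(offer, norm_used, params)
    as.integer(stats::runif(1) < stats::plogis(params$beta * q))
  }
}

#' Simulate a full cohort of forward-thinking agents
#'
#' Draws `n_subjects` parameter sets from the generating distribution and
#' plays each agent through one session of the specified environment; the
#' agent chooses by Bernoulli draws from its softmax acceptance
#' probability. Deterministic given `seed`.
#'
#' @param spec a [population_spec()].
#' @param seed integer master seed.
#' @param id_prefix subject-id prefix.
#' @return List with `sessions` (list of [session_data()]) and `ledger`, a
#'   tibble mapping subject_id to the generating parameters.
#' @export
simulate_cohort <- function(spec, seed = 1L, id_prefix = "sim") {
  params <- sample_params(spec, seed = seed)
  ids <- sprintf("%s%03d", id_prefix, seq_len(spec$n_subjects))
  sessions <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sessions[[i]] <- run_session(ft_policy(params[[i]]), spec$env,
                                 subject_id = ids[i],
                                 seed = (as.numeric(seed) + 7919 * i) %% 2147483647)
  }
  ledger <- tibble::tibble(
    subject_id = ids,
    condition = spec$env$condition,
    beta = vapply(params, `[[`, 0, "beta"),
    alpha = vapply(params, `[[`, 0, "alpha"),
    f0 = vapply(params, `[[`, 0, "f0"),
    eps = vapply(params, `[[`, 0, "eps"),
    delta = vapply(params, `[[`, 0, "delta"),
    gamma = spec$gamma, n_steps = spec$horizon, seed = seed)
  list(sessions = sessions, ledger = ledger)
}

#' Is a session a flat responder?
#'
#' Flat responders (all offers accepted or all rejected within a block)
#' carry no choice variability and are excluded from recovery correlations,
#' mirroring the online sample's data-cleaning rule.
#'
#' @param session a [session_data()].
#' @return Logical.
#' @export
is_flat_responder <- function(session) {
  length(unique(session$choices)) == 1L
}
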