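# Two-condition iterated ultimatum-game environments: choice-contingent
# ("controllable") offers and choice-independent ("uncontrollable") offers.

#' Fixed 30-offer list used by the online uncontrollable variant
#'
#' The pre-determined offer multiset presented (in shuffled order) to every
#' subject in the online uncontrollable condition: mean $5.0, sample SD $2.3,
#' range $1--$9.
#'
#' @return Integer vector of length 30.
#' @export
fixed_offer_list <- function() {
  c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L,
    5L, 5L, 5L, 6L, 6L, 6L, 6L, 7L, 7L, 7L, 8L, 8L, 8L, 9L, 9L)
}

#' Environment configuration for one condition block
#'
#' @param condition one of `"controllable"`, `"uncontrollable_gaussian"`,
#'   `"uncontrollable_fixed"`.
#' @param n_trials trials per block: 40 for the laboratory (fMRI) variant,
#'   30 for the online variant.
#' @param first_offer opening offer in dollars; the two generative conditions
#'   always open at $5. Ignored for the fixed-list condition, whose first
#'   offer is the first element of the (possibly shuffled) list.
#' @param offer_min,offer_max dollar bounds on presented offers. Defaults per
#'   condition: controllable 1/9, gaussian 2/8, fixed list 1/9.
#' @param step_magnitudes candidate dollar steps for the controllable rule.
#' @param step_probabilities probabilities of each step; must sum to 1.
#' @param gaussian_mu,gaussian_sigma truncated-Gaussian moments for the
#'   uncontrollable generator (before rounding/clipping).
#' @param offer_list fixed offer list for `"uncontrollable_fixed"`.
#' @param shuffle_fixed_list randomize the fixed list order?
#' @return An object of class `env_config`.
#' @export
env_config <- function(condition = c("controllable", "uncontrollable_gaussian",
                                     "uncontrollable_fixed"),
                       n_trials = 40L,
                       first_offer = 5L,
                       offer_min = NULL,
                       offer_max = NULL,
                       step_magnitudes = c(0L, 1L, 2L),
                       step_probabilities = rep(1 / 3, 3),
                       gaussian_mu = 5,
                       gaussian_sigma = 1.2,
                       offer_list = fixed_offer_list(),
                       shuffle_fixed_list = TRUE) {
  condition <- match.arg(condition)
  if (is.null(offer_min))
    offer_min <- if (condition == "uncontrollable_gaussian") 2L else 1L
  if (is.null(offer_max))
    offer_max <- if (condition == "uncontrollable_gaussian") 8L else 9L
  if (condition == "uncontrollable_fixed")
    n_trials <- length(offer_list)

  stopifnot(
    n_trials >= 1,
    length(step_magnitudes) == length(step_probabilities),
    abs(sum(step_probabilities) - 1) < 1e-12,
    offer_min <= first_offer, first_offer <= offer_max
  )
  if (condition == "uncontrollable_fixed" &&
      (any(offer_list < offer_min) || any(offer_list > offer_max)))
    stop("fixed offer list values must lie within [offer_min, offer_max]")

  structure(
    list(condition = condition, n_trials = as.integer(n_trials),
         first_offer = as.integer(first_offer),
         offer_min = as.integer(offer_min), offer_max = as.integer(offer_max),
         step_magnitudes = as.integer(step_magnitudes),
         step_probabilities = step_probabilities,
         gaussian_mu = gaussian_mu, gaussian_sigma = gaussian_sigma,
         offer_list = as.integer(offer_list),
         shuffle_fixed_list = isTRUE(shuffle_fixed_list)),
    class = "env_config")
}

#' Next offer under the controllable contingency
#'
#' Rejecting raises and accepting lowers the partner's next offer by a step
#' drawn uniformly from $\{0, 1, 2\}$; the result is clamped into the $1--$9
#' range. The step is sampled first and the sum clamped (rather than
#' renormalizing over feasible steps at the boundaries).
#'
#' Draws from the current R random stream; seed with [set.seed()].
#'
#' @param current_offer integer dollars in `[1, 9]`.
#' @param choice 0 = reject, 1 = accept.
#' @param config an [env_config()] (controllable).
#' @return Integer next offer in `[1, 9]`.
#' @export
next_offer_controllable <- function(current_offer, choice,
                                    config = env_config("controllable")) {
  if (!(length(choice) == 1L && choice %in% c(0, 1)))
    stop("choice must be 0 (reject) or 1 (accept)")
  stopifnot(current_offer >= config$offer_min,
            current_offer <= config$offer_max)
  d <- sample(config$step_magnitudes, 1L, prob = config$step_probabilities)
  raw <- if (choice == 0) current_offer + d else current_offer - d
  as.integer(min(max(raw, config$offer_min), config$offer_max))
}

#' Draw one uncontrollable offer from the rounded truncated Gaussian
#'
#' Normal(5, 1.2), rounded to the nearest integer, then clipped into
#' `[2, 8]` (round first, then clip; out-of-range values are not redrawn).
#'
#' @param config an [env_config()] (uncontrollable_gaussian).
#' @param n number of draws.
#' @return Integer vector of offers in `[2, 8]`.
#' @export
draw_offer_uncontrollable_gaussian <- function(config = env_config("uncontrollable_gaussian"),
                                               n = 1L) {
  x <- round(stats::rnorm(n, config$gaussian_mu, config$gaussian_sigma))
  as.integer(pmin(pmax(x, config$offer_min), config$offer_max))
}

#' Build the offer sequence for the fixed-list uncontrollable condition
#'
#' Returns a permutation of the configured list (the printed order when
#' shuffling is disabled); the offer multiset is always preserved.
#'
#' @param config an [env_config()] with `condition = "uncontrollable_fixed"`.
#' @return Integer vector of length `n_trials`.
#' @export
make_fixed_offer_sequence <- function(config) {
  if (config$condition != "uncontrollable_fixed")
    stop("config$condition must be 'uncontrollable_fixed'")
  if (length(config$offer_list) != config$n_trials)
    stop("fixed offer list length (", length(config$offer_list),
         ") does not match n_trials (", config$n_trials, ")")
  if (config$shuffle_fixed_list) sample(config$offer_list) else config$offer_list
}

#' Session record for one subject in one condition block
#'
#' @param subject_id character id.
#' @param condition condition label (see [env_config()]).
#' @param offers integer offers, one per trial.
#' @param choices 0/1 choices, one per trial.
#' @param block_order optional integer block position.
#' @return A `session_data` object (a list).
#' @export
session_data <- function(subject_id, condition, offers, choices,
                         block_order = NA_integer_) {
  offers <- as.integer(offers)
  choices <- as.integer(choices)
  if (length(offers) != length(choices))
    stop("offers and choices must have equal length")
  if (!all(choices %in% c(0L, 1L)))
    stop("choices must be 0 (reject) or 1 (accept)")
  lim <- offer_range(condition)
  if (any(offers < lim[1]) || any(offers > lim[2]))
    stop("offers outside [", lim[1], ", ", lim[2], "] for condition ", condition)
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         offers = offers, choices = choices,
         block_order = as.integer(block_order)),
    class = "session_data")
}

offer_range <- function(condition) {
  switch(condition,
         controllable = c(1L, 9L),
         uncontrollable_gaussian = c(2L, 8L),
         uncontrollable_fixed = c(1L, 9L),
         stop("unknown condition: ", condition))
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> subject %s, %s, %d trials, %.0f%% accepted\n",
              x$subject_id, x$condition, length(x$offers),
              100 * mean(x$choices)))
  invisible(x)
}

#' Run one session of the task against a choice policy
#'
#' Plays the trial loop: present the offer, query the policy for an
#' accept/reject choice, then generate the next offer under the condition's
#' rule. The two generative conditions open at the configured $5 first offer;
#' the fixed-list condition presents its (possibly shuffled) list regardless
#' of choices.
#'
#' Stochastic components use the current R random stream unless `seed` is
#' given.
#'
#' @param policy `function(offer, trial) -> 0 or 1`.
#' @param config an [env_config()].
#' @param subject_id id stored in the returned session.
#' @param seed optional integer seed applied before any draw.
#' @return A [session_data()] object.
#' @export
run_session <- function(policy, config, subject_id = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  offers <- integer(n)
  choices <- integer(n)
  # Choice-independent offer streams are generated up front, so two runs
  # with the same seed and different policies see identical offers.
  pre <- switch(config$condition,
                uncontrollable_fixed = make_fixed_offer_sequence(config),
                uncontrollable_gaussian =
                  c(config$first_offer,
                    draw_offer_uncontrollable_gaussian(config, n - 1L)),
                NULL)

  for (t in seq_len(n)) {
    offers[t] <- if (!is.null(pre)) {
      pre[t]
    } else if (t == 1L) {
      config$first_offer
    } else {
      next_offer_controllable(offers[t - 1L], choices[t - 1L], config)
    }
    ch <- policy(offers[t], t)
    if (length(ch) != 1L || !ch %in% c(0, 1))
      stop("policy returned a non-binary choice at trial ", t)
    choices[t] <- as.integer(ch)
  }
  session_data(subject_id, config$condition, offers, choices)
}
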