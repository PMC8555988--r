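# Per-subject bounded maximum-likelihood estimation, information-criterion
# scoring, horizon comparison and choice-prediction accuracy.

#' Fitting configuration
#'
#' @param n_restarts number of Latin-hypercube multi-start restarts.
#' @param exclude_first,exclude_last fit-window rule (default: drop 5 at
#'   each end, leaving 30 of 40 or 20 of 30 trials).
#' @param reltol relative convergence tolerance passed to the optimizer.
#' @param maxit maximum optimizer iterations per restart.
#' @param seed integer seed for the restart design.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_restarts = 20L, exclude_first = 5L,
                       exclude_last = 5L, reltol = 1e-6, maxit = 500L,
                       seed = 1L) {
  stopifnot(n_restarts >= 1)
  structure(list(n_restarts = as.integer(n_restarts),
                 exclude_first = as.integer(exclude_first),
                 exclude_last = as.integer(exclude_last),
                 reltol = reltol, maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Map unconstrained reals onto the bounded parameter space (and back)
#'
#' Each free parameter is `lo + (hi - lo) * logistic(x)`, the scaled-sigmoid
#' constraint used for all five parameters (e.g. delta onto `[-2, 2]`).
#' `untransform_params()` is the exact inverse; parameters at (or beyond
#' machine resolution of) the bounds map to +/-36, where the logistic has
#' saturated.
#'
#' @param x numeric 5-vector (beta, alpha, f0, eps, delta) in unconstrained
#'   space.
#' @param gamma,n_steps fixed components of the resulting [ft_params()].
#' @return `transform_params()`: an [ft_params()]; `untransform_params()`:
#'   a numeric 5-vector.
#' @export
transform_params <- function(x, gamma = 0.8, n_steps = 2L) {
  stopifnot(length(x) == 5, all(is.finite(x)))
  v <- vapply(seq_along(FT_BOUNDS), function(i) {
    b <- FT_BOUNDS[[i]]
    b[1] + (b[2] - b[1]) * stats::plogis(x[i])
  }, 0)
  ft_params(beta = v[1], alpha = v[2], f0 = v[3], eps = v[4], delta = v[5],
            gamma = gamma, n_steps = n_steps)
}

#' @rdname transform_params
#' @param params an [ft_params()].
#' @export
untransform_params <- function(params) {
  vapply(names(FT_BOUNDS), function(nm) {
    b <- FT_BOUNDS[[nm]]
    u <- (params[[nm]] - b[1]) / (b[2] - b[1])
    min(max(stats::qlogis(u), -36), 36)
  }, 0, USE.NAMES = FALSE)
}

#' Fit the forward-thinking model to one subject's session
#'
#' Minimizes the session's negative log-likelihood over the five free
#' parameters (gamma fixed) in the unconstrained sigmoid-transformed space,
#' from `n_restarts` Latin-hypercube start points, with derivative-free
#' Nelder-Mead local search. The best restart is returned along with the
#' spread of converged restart optima (a multimodality diagnostic).
#'
#' @param session a [session_data()].
#' @param n_steps planning horizon to fit.
#' @param config a [fit_config()].
#' @param norm_timing see [norm_trajectory()].
#' @return A `fit_result` list: `params_hat`, `neg_loglik`, `dic`,
#'   `n_fit_trials`, `accuracy`, `converged`, `restart_spread`,
#'   `n_restarts_ok`.
#' @export
fit_subject <- function(session, n_steps = 2L, config = fit_config(),
                        norm_timing = "before") {
  window <- fit_window(length(session$offers),
                       config$exclude_first, config$exclude_last)
  obj <- function(x) {
    session_loglik(session, transform_params(x, n_steps = n_steps),
                   window, norm_timing)
  }
  set.seed(config$seed)
  # LHS design on the interior of the box, mapped to unconstrained space
  u <- 0.02 + 0.96 * lhs::randomLHS(config$n_restarts, 5)
  starts <- stats::qlogis(u)

  best <- NULL
  vals <- rep(NA_real_, config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    opt <- tryCatch(
      stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    vals[r] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all ", config$n_restarts, " restarts failed for subject ",
         session$subject_id)

  params_hat <- transform_params(best$par, n_steps = n_steps)
  nll <- best$value
  list(subject_id = session$subject_id,
       condition = session$condition,
       params_hat = params_hat,
       neg_loglik = nll,
       dic = dic_score(nll, k_params = 5L, n_trials = length(window)),
       n_fit_trials = length(window),
       accuracy = prediction_accuracy(session, params_hat, window,
                                      norm_timing),
       converged = best$convergence == 0,
       restart_spread = if (sum(!is.na(vals)) > 1)
         diff(range(vals, na.rm = TRUE)) else 0,
       n_restarts_ok = sum(!is.na(vals)))
}

#' Penalized model-fit score (Draper's information criterion)
#'
#' `2 * negLL + k * (ln n - ln 2 pi)`; lower is better. The additive
#' constant convention is isolated here so it can be swapped; horizon
#' orderings are unaffected by it.
#'
#' @param neg_loglik negative log-likelihood at the optimum.
#' @param k_params number of free parameters (5 for this model).
#' @param n_trials number of fitted trials.
#' @return Scalar score.
#' @export
dic_score <- function(neg_loglik, k_params = 5L, n_trials) {
  stopifnot(n_trials >= 1)
  2 * neg_loglik + k_params * (log(n_trials) - log(2 * pi))
}

#' Choice-prediction accuracy of fitted parameters
#'
#' The model's predicted choice is accept iff the acceptance probability
#' exceeds 0.5 (a tie predicts reject); accuracy is the fraction of
#' fit-window trials where prediction matches the observed choice.
#'
#' @inheritParams session_loglik
#' @return Fraction in `[0, 1]`.
#' @export
prediction_accuracy <- function(session, params, window = NULL,
                                norm_timing = "before") {
  if (is.null(window)) window <- fit_window(length(session$offers))
  nt <- norm_trajectory(session$offers, params$f0, params$eps, norm_timing)
  q <- session_Q(session$offers, nt$norm_used, params)
  p <- stats::plogis(params$beta * q)
  predicted <- as.integer(p > 0.5)
  mean(predicted[window] == session$choices[window])
}

#' Fit every subject at every planning horizon and compare fits
#'
#' Fits each session at each horizon, tabulates per-subject DIC scores, and
#' runs paired t-tests of each horizon's DIC against a reference horizon
#' (default 2). Fit failures are recorded as NA cells and dropped pairwise
#' from the tests.
#'
#' @param sessions list of [session_data()].
#' @param horizons integer planning horizons to fit.
#' @param config a [fit_config()].
#' @param reference horizon the t-tests compare against.
#' @return List with `dic` (tibble subject x horizon), `fits` (nested list
#'   of fit results), `mean_dic` (named vector), and `t_tests` (tibble of
#'   paired comparisons vs the reference horizon).
#' @export
compare_horizons <- function(sessions, horizons = 0:4,
                             config = fit_config(), reference = 2L) {
  stopifnot(length(sessions) >= 2, length(horizons) >= 1)
  fits <- lapply(horizons, function(h)
    lapply(sessions, function(s)
      tryCatch(fit_subject(s, n_steps = h, config = config),
               error = function(e) NULL)))
  names(fits) <- paste0("h", horizons)
  dic <- sapply(fits, function(col)
    vapply(col, function(f) if (is.null(f)) NA_real_ else f$dic, 0))
  dic_tbl <- tibble::as_tibble(as.data.frame(dic))
  dic_tbl$subject_id <- vapply(sessions, `[[`, "", "subject_id")

  tt <- NULL
  ref_col <- paste0("h", reference)
  if (reference %in% horizons) {
    others <- setdiff(horizons, reference)
    tt <- do.call(rbind, lapply(others, function(h) {
      a <- dic[, ref_col]
      b <- dic[, paste0("h", h)]
      keep <- is.finite(a) & is.finite(b)
      if (sum(keep) < 2 || stats::sd(a[keep] - b[keep]) == 0) {
        tibble::tibble(horizon = h, reference = reference,
                       t = if (sum(keep) >= 2) 0 else NA_real_,
                       df = sum(keep) - 1, p = NA_real_)
      } else {
        ht <- stats::t.test(a[keep], b[keep], paired = TRUE)
        tibble::tibble(horizon = h, reference = reference,
                       t = unname(ht$statistic), df = unname(ht$parameter),
                       p = ht$p.value)
      }
    }))
  }
  list(dic = dic_tbl, fits = fits,
       mean_dic = colMeans(dic, na.rm = TRUE), t_tests = tt)
}
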