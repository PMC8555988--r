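# Parameter- and model-recovery pipelines: simulate agents with known
# parameters, refit, and quantify identifiability.

#' Parameter recovery for one condition and horizon
#'
#' Simulates a cohort from the generating distribution, fits every agent at
#' the same horizon, and correlates recovered with generating values per
#' parameter. Flat responders (all-accept or all-reject sessions) are
#' excluded from the correlations and counted; fit failures likewise.
#'
#' @param spec a [population_spec()].
#' @param config a [fit_config()].
#' @param horizon planning horizon used for both generation and fitting
#'   (default: the spec's horizon).
#' @param seed master seed for the simulation.
#' @return A `recovery_report` list: `params` (tibble of generating and
#'   recovered values per subject), `correlations` (tibble with Pearson r,
#'   its CI and p, and Spearman rho per parameter), `n_flat`, `n_failed`,
#'   `horizon`, `condition`, `seed`.
#' @export
run_parameter_recovery <- function(spec, config = fit_config(),
                                   horizon = spec$horizon, seed = 1L) {
  cohort <- simulate_cohort(spec, seed = seed)
  flat <- vapply(cohort$sessions, is_flat_responder, TRUE)

  fits <- lapply(cohort$sessions, function(s) {
    if (is_flat_responder(s)) return(NULL)
    tryCatch(fit_subject(s, n_steps = horizon, config = config),
             error = function(e) NULL)
  })
  failed <- !flat & vapply(fits, is.null, TRUE)

  rec <- function(nm) vapply(fits, function(f)
    if (is.null(f)) NA_real_ else f$params_hat[[nm]], 0)
  par_names <- names(FT_BOUNDS)
  params <- cohort$ledger[c("subject_id", par_names)]
  names(params)[-1] <- paste0("gen_", par_names)
  for (nm in par_names) params[[paste0("rec_", nm)]] <- rec(nm)
  params$flat <- flat
  params$accuracy <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else f$accuracy, 0)

  correlations <- do.call(rbind, lapply(par_names, function(nm) {
    g <- params[[paste0("gen_", nm)]]
    r <- params[[paste0("rec_", nm)]]
    keep <- !flat & is.finite(r)
    if (sum(keep) < 3 || stats::sd(g[keep]) == 0 || stats::sd(r[keep]) == 0)
      return(tibble::tibble(parameter = nm, r = NA_real_, r_lo = NA_real_,
                            r_hi = NA_real_, p = NA_real_,
                            spearman = NA_real_, n = sum(keep)))
    ct <- stats::cor.test(g[keep], r[keep])
    rho <- stats::cor(g[keep], r[keep], method = "spearman")
    tibble::tibble(parameter = nm, r = unname(ct$estimate),
                   r_lo = ct$conf.int[1], r_hi = ct$conf.int[2],
                   p = ct$p.value, spearman = rho, n = sum(keep))
  }))

  structure(list(params = params, correlations = correlations,
                 n_flat = sum(flat), n_failed = sum(failed),
                 horizon = horizon, condition = spec$env$condition,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s, horizon %d, n = %d (%d flat, %d failed)\n",
              x$condition, x$horizon, nrow(x$params), x$n_flat, x$n_failed))
  print(as.data.frame(x$correlations), digits = 3)
  invisible(x)
}

#' Model recovery across planning horizons
#'
#' For cohorts generated at each candidate horizon, fits all candidate
#' horizons to every agent and tabulates the fraction of agents whose
#' best (lowest-DIC) model is each fitted horizon.
#'
#' @param spec a [population_spec()]; its `horizon` field is overridden by
#'   each generating horizon in turn.
#' @param config a [fit_config()].
#' @param horizons integer set of horizons (>= 2 of them).
#' @param seed master seed.
#' @return List with `confusion` (matrix, generating x fitted, rows sum to
#'   1 over fitted models), `mean_dic` (matrix of per-cohort mean DIC), and
#'   `detail` (per-cohort [compare_horizons()] outputs).
#' @export
run_model_recovery <- function(spec, config = fit_config(),
                               horizons = c(0L, 2L), seed = 1L) {
  stopifnot(length(horizons) >= 2)
  hn <- paste0("h", horizons)
  confusion <- matrix(NA_real_, length(horizons), length(horizons),
                      dimnames = list(generating = hn, fitted = hn))
  mean_dic <- confusion
  detail <- vector("list", length(horizons))
  names(detail) <- hn

  for (gi in seq_along(horizons)) {
    gspec <- spec
    gspec$horizon <- horizons[gi]
    cohort <- simulate_cohort(gspec, seed = seed + gi)
    keep <- !vapply(cohort$sessions, is_flat_responder, TRUE)
    cmp <- compare_horizons(cohort$sessions[keep], horizons = horizons,
                            config = config,
                            reference = horizons[gi])
    dic <- as.matrix(cmp$dic[hn])
    best <- apply(dic, 1, function(row)
      if (all(is.finite(row))) which.min(row) else NA_integer_)
    tab <- tabulate(best[!is.na(best)], nbins = length(horizons))
    confusion[gi, ] <- tab / sum(tab)
    mean_dic[gi, ] <- colMeans(dic, na.rm = TRUE)
    detail[[gi]] <- cmp
  }
  list(confusion = confusion, mean_dic = mean_dic, detail = detail)
}
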