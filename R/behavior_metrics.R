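# Model-agnostic behavioral summaries (mean offers, trajectories, binned
# rejection rates) and the associated group tests.

OFFER_BINS <- list(low = 1:3, medium = 4:6, high = 7:9)

#' Summarize a cohort's behavior without reference to any model
#'
#' Per subject: mean received offer, overall rejection rate, and rejection
#' rates within the low ($1-3), medium ($4-6) and high ($7-9) offer bins
#' (computed only over trials whose offer falls in the bin; subjects with
#' no trial in a bin get NA there, with the occupancy count recorded).
#' Across subjects: the per-trial mean-offer trajectory with SEM.
#'
#' @param sessions nonempty list of [session_data()].
#' @return A `cohort_summary` list: `subjects` (tibble), `trajectory`
#'   (tibble trial / mean_offer / sem / n), `conditions`.
#' @export
summarize_cohort <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  subjects <- do.call(rbind, lapply(sessions, function(s) {
    rej <- 1L - s$choices
    row <- tibble::tibble(
      subject_id = s$subject_id, condition = s$condition,
      n_trials = length(s$offers),
      mean_offer = mean(s$offers),
      rejection_rate = mean(rej))
    for (bn in names(OFFER_BINS)) {
      in_bin <- s$offers %in% OFFER_BINS[[bn]]
      row[[paste0("reject_", bn)]] <-
        if (any(in_bin)) mean(rej[in_bin]) else NA_real_
      row[[paste0("n_", bn)]] <- sum(in_bin)
    }
    row
  }))

  n_max <- max(subjects$n_trials)
  offer_mat <- vapply(sessions, function(s)
    c(s$offers, rep(NA_real_, n_max - length(s$offers))), numeric(n_max))
  offer_mat <- matrix(offer_mat, nrow = n_max)
  n_per <- rowSums(!is.na(offer_mat))
  trajectory <- tibble::tibble(
    trial = seq_len(n_max),
    mean_offer = rowMeans(offer_mat, na.rm = TRUE),
    sem = apply(offer_mat, 1, stats::sd, na.rm = TRUE) / sqrt(n_per),
    n = n_per)

  structure(list(subjects = subjects, trajectory = trajectory,
                 conditions = unique(subjects$condition)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects (%s)\n", nrow(x$subjects),
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  mean offer %.2f, rejection rate %.2f\n",
              mean(x$subjects$mean_offer), mean(x$subjects$rejection_rate)))
  invisible(x)
}

#' Group comparison of per-subject scalars
#'
#' Unpaired comparisons use Welch's t-test with Satterthwaite's
#' degrees-of-freedom approximation (unequal variances assumed); paired
#' comparisons use the paired t-test. Degenerate inputs (no variance
#' anywhere) raise an error rather than returning an undefined statistic.
#'
#' @param values_a,values_b numeric vectors of per-subject values (equal
#'   length when `paired`).
#' @param paired logical.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `paired`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (paired && length(values_a) != length(values_b))
    stop("paired comparison requires equal-length vectors")
  degenerate <- if (paired)
    stats::sd(values_a - values_b) == 0
  else
    stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (degenerate)
    stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values_a, values_b, paired = paired,
                      var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(values_a), mean_b = mean(values_b),
       paired = paired)
}

#' Binned rejection-rate contrast between two cohorts
#'
#' For each offer bin, compares per-subject binned rejection rates between
#' cohorts with Welch t-tests, excluding subjects who never saw an offer in
#' that bin (their rate is undefined, not imputed).
#'
#' @param summary_a,summary_b [summarize_cohort()] outputs.
#' @return Tibble: bin, per-group n and mean rate, t, df, p.
#' @export
compare_binned_rejection <- function(summary_a, summary_b) {
  do.call(rbind, lapply(names(OFFER_BINS), function(bn) {
    a <- summary_a$subjects[[paste0("reject_", bn)]]
    b <- summary_b$subjects[[paste0("reject_", bn)]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    res <- if (length(a) >= 2 && length(b) >= 2 &&
               !(stats::sd(a) == 0 && stats::sd(b) == 0))
      compare_groups(a, b)
    else
      list(t = NA_real_, df = NA_real_, p = NA_real_,
           mean_a = mean(a), mean_b = mean(b))
    tibble::tibble(bin = bn, n_a = length(a), n_b = length(b),
                   rate_a = res$mean_a, rate_b = res$mean_b,
                   t = res$t, df = res$df, p = res$p)
  }))
}
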