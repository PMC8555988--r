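# Readers/writers for the session and parameter-ledger CSV schemas.
#
# Session CSV, one row per trial:
#   subject_id, condition, trial (1-based), offer (integer), choice (0/1),
#   emotion (may be empty), block_order (may be empty)

SESSION_COLUMNS <- c("subject_id", "condition", "trial", "offer", "choice",
                     "emotion", "block_order")

#' Write sessions to a session CSV
#'
#' @param sessions list of [session_data()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, condition = s$condition,
               trial = seq_along(s$offers), offer = s$offers,
               choice = s$choices, emotion = NA_real_,
               block_order = s$block_order)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read sessions from a session CSV
#'
#' Validates the schema and every session invariant (integer offers within
#' the condition's range, binary choices, contiguous 1-based trial
#' numbering), reporting the offending row on failure. A write/read round
#' trip reproduces offers and choices exactly.
#'
#' @param path CSV path.
#' @return List of [session_data()].
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(SESSION_COLUMNS, c("emotion", "block_order")),
                     names(df))
  if (length(missing))
    stop("session CSV missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!df$choice %in% c(0L, 1L))
  if (length(bad))
    stop("non-binary choice at row ", bad[1], " (choice = ",
         df$choice[bad[1]], ")")
  bad <- which(df$offer != round(df$offer))
  if (length(bad))
    stop("non-integer offer at row ", bad[1])
  lim <- t(vapply(df$condition, offer_range, integer(2)))
  bad <- which(df$offer < lim[, 1] | df$offer > lim[, 2])
  if (length(bad))
    stop("offer ", df$offer[bad[1]], " at row ", bad[1],
         " outside the ", df$condition[bad[1]], " range [",
         lim[bad[1], 1], ", ", lim[bad[1], 2], "]")

  keys <- unique(df[c("subject_id", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$subject_id == keys$subject_id[i] &
                df$condition == keys$condition[i], ]
    sub <- sub[order(sub$trial), ]
    if (!identical(as.integer(sub$trial), seq_len(nrow(sub))))
      stop("non-contiguous trial numbering for subject ",
           keys$subject_id[i], " (", keys$condition[i], ")")
    session_data(keys$subject_id[i], keys$condition[i],
                 sub$offer, sub$choice,
                 block_order = if ("block_order" %in% names(sub))
                   sub$block_order[1] else NA_integer_)
  })
}

#' Write / read the generating-parameter ledger CSV
#'
#' Columns: subject_id, condition, beta, alpha, f0, eps, delta, gamma,
#' n_steps, seed.
#'
#' @param ledger tibble as produced by [simulate_cohort()].
#' @param path CSV path.
#' @return `write_params_ledger()`: `path` invisibly;
#'   `read_params_ledger()`: a tibble.
#' @export
write_params_ledger <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_ledger
#' @export
read_params_ledger <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
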