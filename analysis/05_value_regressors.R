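#!/usr/bin/env Rscript
# Export trial-level value regressors (z-scored total value of the chosen
# action, plus its current/future decomposition, the norm and the norm
# prediction error) for every recovered subject -- the quantities that
# would enter a model-based neural analysis as parametric modulators.

library(socialFT)

for (cond in c("controllable", "uncontrollable")) {
  sessions <- read_sessions(sprintf("results/sessions_%s.csv", cond))
  rec <- read.csv(sprintf("results/recovery_params_%s.csv", cond))
  out <- list()
  for (s in sessions) {
    row <- rec[rec$subject_id == s$subject_id, ]
    if (nrow(row) != 1 || !is.finite(row$rec_beta)) next
    p <- ft_params(row$rec_beta, row$rec_alpha, row$rec_f0, row$rec_eps,
                   row$rec_delta, n_steps = 2)
    out[[s$subject_id]] <- suppressWarnings(export_value_regressors(s, p))
  }
  reg <- do.call(rbind, out)
  write.csv(reg, sprintf("results/value_regressors_%s.csv", cond),
            row.names = FALSE)
  message(sprintf("%s: regressors for %d subjects (%d trials)",
                  cond, length(out), nrow(reg)))
}
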