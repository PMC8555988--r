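#!/usr/bin/env Rscript
# Model-agnostic behavioral summaries of the simulated cohorts: per-subject
# mean offers, offer trajectories, and rejection rates binned by offer size
# (low $1-3 / medium $4-6 / high $7-9), with Welch tests between conditions.

library(socialFT)

ctrl <- read_sessions("results/sessions_controllable.csv")
unc <- read_sessions("results/sessions_uncontrollable.csv")
sum_c <- summarize_cohort(ctrl)
sum_u <- summarize_cohort(unc)

write.csv(rbind(sum_c$subjects, sum_u$subjects),
          "results/behavior_subjects.csv", row.names = FALSE)
traj <- rbind(cbind(condition = "controllable", sum_c$trajectory),
              cbind(condition = "uncontrollable", sum_u$trajectory))
write.csv(traj, "results/behavior_trajectory.csv", row.names = FALSE)

mo <- compare_groups(sum_c$subjects$mean_offer, sum_u$subjects$mean_offer)
message(sprintf(
  "mean offer: controllable %.2f vs uncontrollable %.2f (Welch t = %.2f, df = %.1f, p = %.2g)",
  mo$mean_a, mo$mean_b, mo$t, mo$df, mo$p))

bins <- compare_binned_rejection(sum_c, sum_u)
write.csv(bins, "results/behavior_binned_rejection.csv", row.names = FALSE)
for (i in seq_len(nrow(bins)))
  message(sprintf(
    "rejection (%s offers): %.0f%% vs %.0f%% (t = %.2f, p = %.2g)",
    bins$bin[i], 100 * bins$rate_a[i], 100 * bins$rate_b[i],
    bins$t[i], bins$p[i]))
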