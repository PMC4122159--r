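#!/usr/bin/env Rscript
# Go/no-go behavioral scoring from the simulated trial logs: per-session
# percent correct and d-prime, stage-advancement decisions (d' >= 1.5 for
# 10 consecutive sessions), and across-subject learning curves.
# Writes results/behavior_curves.csv and results/stage_advancement.csv.

library(aafdiscrim)

out <- "results"
curve_rows <- list(); stage_rows <- list()
crit <- stage_criteria("dprime", 1.5, 10)
for (g in group_labels()) for (task in c("consonant", "vowel")) {
  log <- read_behavior_log(file.path(out, "data",
                                     paste0(g, "_", task, "_trials.csv")))
  # recover subject/session structure from the session ids (subj_sNN)
  log$subject_id <- sub("_s\\d+$", "", log$session_id)
  log$session_index <- as.integer(sub("^.*_s", "", log$session_id))
  cv <- learning_curve(log)
  cv$group <- g; cv$task <- task
  curve_rows[[length(curve_rows) + 1L]] <- cv
  for (subj in unique(log$subject_id)) {
    d <- vapply(sort(unique(log$session_index)), function(s)
      score_session(log[log$subject_id == subj &
                          log$session_index == s, ])$d_prime, numeric(1))
    adv <- evaluate_stage(d, crit)
    stage_rows[[length(stage_rows) + 1L]] <- data.frame(
      group = g, task = task, subject_id = subj,
      advanced = adv$advanced, session_index = adv$session_index)
  }
}
curves <- do.call(rbind, curve_rows)
stages <- do.call(rbind, stage_rows)
utils::write.csv(curves, file.path(out, "behavior_curves.csv"),
                 row.names = FALSE)
utils::write.csv(stages, file.path(out, "stage_advancement.csv"),
                 row.names = FALSE)
late <- curves[curves$session_index >= 10, ]
cat("asymptotic (sessions 10-15) percent correct by group and task:\n")
print(aggregate(mean_percent_correct ~ group + task, late, mean),
      row.names = FALSE, digits = 3)
cat("subjects reaching d' >= 1.5 x 10 consecutive sessions:\n")
print(aggregate(advanced ~ group + task, stages, mean),
      row.names = FALSE, digits = 2)
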