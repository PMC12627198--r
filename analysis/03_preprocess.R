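#!/usr/bin/env Rscript
# Exclusion cascade on the simulated cohort: catch-trial errors (>= 2
# excludes everywhere), RT outliers (< 300 ms or > 10 s; >= 10% excludes
# from the DDM analyses), and total preference switches (>= 100 excludes
# from the DDM analyses).

suppressPackageStartupMessages(library(ambiddm))

beh <- read.csv("results/cohort_behavior.csv")
report <- apply_exclusions(beh)
kept <- ddm_ready_trials(beh, report)

cat(sprintf("participants: %d | GLMM-eligible: %d | DDM-eligible: %d\n",
            nrow(report), sum(report$included_glmm),
            sum(report$included_ddm)))
cat(sprintf("mean outlier share: %.1f%% | trials entering the DDM: %d\n",
            100 * mean(report$pct_outlier_trials), nrow(kept)))

write.csv(report, "results/eligibility_report.csv", row.names = FALSE)
write.csv(kept, "results/ddm_trials.csv", row.names = FALSE)
jsonlite::write_json(
  list(n_participants = nrow(report),
       n_glmm = sum(report$included_glmm),
       n_ddm = sum(report$included_ddm),
       n_ddm_trials = nrow(kept)),
  "results/exclusion_summary.json", auto_unbox = TRUE)
cat("wrote results/eligibility_report.csv, ddm_trials.csv,",
    "exclusion_summary.json\n")
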