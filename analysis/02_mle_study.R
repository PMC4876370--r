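#!/usr/bin/env Rscript
# Step 2: the maximum-likelihood arm of the study over the full
# 40-condition grid at reduced replications (R = 150 per condition keeps
# this a coffee-break run; the acceptance script pushes the headline
# cells to R = 2000). Writes one tidy summary row per condition x
# estimator and prints the qualitative findings.

suppressPackageStartupMessages(library(mlar1sim))
dir.create("results", showWarnings = FALSE)

cfg <- study_config(replications = 150, estimators = c("MLE-F", "MLE-R"),
                    master_seed = 20260923,
                    out_dir = "results/mle_cells")
summ <- run_study(cfg)
write_records(summ, "results/mle_summaries.csv")
cat(sprintf("wrote %d condition summaries to results/mle_summaries.csv\n",
            nrow(summ)))

mr <- summ[summ$estimator == "MLE-R", ]
mf <- summ[summ$estimator == "MLE-F", ]

cat("\n-- findings at reduced replications --\n")
cat(sprintf("mean |bias| of the population autocorrelation: MLE-R %.3f, MLE-F %.3f\n",
            mean(abs(mr$bias_gamma01)), mean(abs(mf$bias_gamma01))))
cat(sprintf("mean power (|gamma01| = 0.6 cells):            MLE-R %.2f, MLE-F %.2f\n",
            mean(mr$epr[abs(mr$gamma01) == 0.6]),
            mean(mf$epr[abs(mf$gamma01) == 0.6])))
cat(sprintf("actual alpha (gamma01 = 0 cells):              MLE-R %.3f, MLE-F %.3f\n",
            mean(mr$epr[mr$gamma01 == 0]), mean(mf$epr[mf$gamma01 == 0])))
cat(sprintf("pct non-stationary predictions, grid mean:     MLE-R %.2f%%\n",
            mean(mr$pct_nonstationary)))
cat("\nThe random estimator shows less bias and far higher power; the\n")
cat("fixed estimator rejects almost never at gamma01 = 0 because its SE\n")
cat("(the mean of per-individual SEs) overstates the variability of the\n")
cat("averaged estimate.\n")
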