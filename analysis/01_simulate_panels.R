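#!/usr/bin/env Rscript
# Step 1: generate example multilevel AR(1) panels and archive them as
# plain text. Demonstrates the generating process (stationary series,
# truncated-normal individual autocorrelations) and the bit-exact
# serialization round trip.

suppressPackageStartupMessages(library(mlar1sim))
dir.create("results/panels", recursive = TRUE, showWarnings = FALSE)

conds <- list(
  easy = mlar1_condition(T = 25, N = 25, gamma01 = 0.3, sigma_u1 = 0.25),
  hard = mlar1_condition(T = 10, N = 10, gamma01 = -0.6, sigma_u1 = 0.40))

for (nm in names(conds)) {
  panel <- generate_panel(conds[[nm]], seed = 20260923)
  print(panel)
  cat(sprintf("  mean true autocorrelation %.3f (population mean %.2f)\n",
              mean(panel$phi_true), conds[[nm]]$gamma01))
  path <- sprintf("results/panels/%s.csv", nm)
  write_panel(panel, path)
  stopifnot(identical(read_panel(path)$scores, panel$scores))
  cat("  archived (and re-read bit-exactly) at", path, "\n")
}

cat("\nNote: at gamma01 = -0.6, sigma_u1 = 0.40 the truncated-normal\n")
cat("draws pile up near the -1 stationarity bound; this is the condition\n")
cat("where the random-effects ML fit produces the most non-stationary\n")
cat("individual predictions downstream.\n")
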