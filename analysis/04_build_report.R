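#!/usr/bin/env Rscript
# Step 4: assemble the per-bundle reliability table (wDSC column plus
# ICC [95% CI] per measure, with significance stars) and the long-form
# CSV report.

suppressMessages(library(tractrel))

root <- "scratch/cohort"
lay <- cohort_layout(root)
rep <- run_reliability(root, "results/report")

cat("\nreport status:", rep$status, "\n")
cat("files:", paste(list.files("results/report"), collapse = ", "), "\n\n")
cat(readLines("results/report/report.md"), sep = "\n")
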