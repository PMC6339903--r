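#!/usr/bin/env Rscript
# Step 1: generate the synthetic paired-session cohort the analyses run
# on: 18 subjects scanned twice, 8 language bundles (AF, ILF, IFOF, UF
# bilaterally) as streamline tubes with a small between-session
# displacement, 7 tract measures per bundle with a known variance-
# components structure, and the right UF missing for one subject.
# Binary outputs (TCK tractograms, NIfTI density maps) go to scratch/.

suppressMessages(library(tractrel))

seed <- 20260926L
root <- "scratch/cohort"

spec <- cohort_sim_spec(seed = seed)
cat("simulating cohort:", length(spec$subjects), "subjects x 2 sessions x",
    length(spec$bundles), "bundles x", length(spec$metrics), "metrics\n")
cat("population ICC of every metric table:",
    true_icc(spec$metric_specs[[1]]), "\n")
simulate_cohort(spec, root)

df <- read.csv(file.path(root, "metrics.csv"))
cat("wrote", root, "with", nrow(df), "metric rows;",
    "right UF present for",
    length(unique(df$subject[df$bundle == "UF_R"])), "of",
    length(spec$subjects), "subjects\n")
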