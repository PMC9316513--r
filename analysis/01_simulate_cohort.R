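#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study cohort.
#
# Emulates the study conditions: 146 COVID-19 survivors with post-COVID
# pain described by 14 variables (13 continuous questionnaire/demographic
# scores plus binary gender), generated from the eight-edge planted
# partial-correlation network with the published Table-of-descriptives
# marginals, and 3 PainDETECT + 3 S-LANSS cells missing completely at
# random.

suppressPackageStartupMessages(library(painnet))
dir.create("results", showWarnings = FALSE)

seed <- 2026
path <- "results/cohort.csv"

simulate_cohort_csv(path, seed = seed)
tab <- read_cohort_csv(path)

cat("Planted network:\n")
print(build_ground_truth())
cat(sprintf("\nWrote %s: %d records x %d variables, %d missing cells\n",
            path, nrow(tab), ncol(tab), sum(is.na(tab))))
cat(sprintf("Male fraction: %.3f  CSI mean (sd): %.1f (%.1f)\n",
            mean(tab$Gender == 0), mean(tab$CSI), sd(tab$CSI)))
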