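#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 500 IDH-wildtype-like subjects,
# three planted subtypes, two partially overlapping modalities (46% both /
# 33% imaging-only / 21% genomics-only), pathway-structured mutations and
# subtype-dependent exponential survival. Writes imaging.csv, genomic.csv,
# clinical.csv and truth.json under results/cohort/.

library(radjoint)

SEED <- 20260401 %% 2147483647
cfg <- synthetic_config(n_subjects = 500, seed = SEED)
cohort <- generate_cohort(cfg)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
radjoint:::write_cohort_csvs(cohort, out)

ds <- cohort$dataset
cat("Simulated cohort written to", out, "\n")
print(ds)
cat(sprintf("availability: both %.1f%% | imaging-only %.1f%% | genomic-only %.1f%%\n",
            100 * mean(ds$has_imaging & ds$has_genomic),
            100 * mean(ds$has_imaging & !ds$has_genomic),
            100 * mean(!ds$has_imaging & ds$has_genomic)))
cat(sprintf("censoring fraction: %.2f (target %.2f)\n",
            mean(cohort$clinical$event == 0), cfg$censoring_rate))
cat(sprintf("planted subtype sizes: %s\n",
            paste(table(cohort$truth$subtype_labels), collapse = " / ")))
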