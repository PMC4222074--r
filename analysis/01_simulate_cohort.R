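#!/usr/bin/env Rscript
# Step 1 — simulate the reference cohort.
#
# Generates the seeded synthetic NSCLC-style cohort (120 subjects, paired
# tumor/normal log2 ratios on 5 chromosomes, 2000 genes, 80 miRNAs, AC/
# SCC/LCC histology) with three planted amplified driver genes carrying
# correlated target modules, one planted driver miRNA and one deletion
# region, and writes it under results/cohort/.

suppressPackageStartupMessages(library(cnadrivers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("Simulated cohort (seed", seed, "):\n")
cat("  subjects:           ", cfg$n_subjects, "\n")
cat("  histology:          ",
    paste(names(table(cohort$labels)), table(cohort$labels),
          collapse = ", "), "\n")
cat("  probes:             ", cfg$n_chromosomes, "chromosomes x",
    cfg$probes_per_chromosome, "probes\n")
cat("  planted drivers:    ",
    paste(cohort$truth$planted_drivers, collapse = ", "),
    "( miRNA:", cohort$truth$planted_driver_mirnas, ")\n")
cat("  planted module sizes:",
    paste(table(cohort$truth$module_membership), collapse = ", "), "\n")
cat("written to results/cohort/\n")
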