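#!/usr/bin/env Rscript
# Step 3 — cohort-level regions.
#
# Finds recurrent CNA regions (>= 10% of subjects with at least one
# call), classifies their polarity under the strict gene rule and the
# relaxed 10%-mixture miRNA rule, runs the histology-differential ANOVA
# on the segmented data, and merges significant regions into clusters
# whose per-state/per-histology aberration frequencies agree within 1
# percentage point.

suppressPackageStartupMessages(library(cnadrivers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cohort <- read_cohort("results/cohort")
dgs <- read_seg("results/calls_dgs.seg")
calls <- data.frame(subject = dgs$sample, chrom = dgs$chrom,
                    start = dgs$loc.start, end_open = dgs$end.open,
                    state = dgs$state)

regions <- find_recurrent_regions(calls, min_recurrence = 0.10)
pol_gene <- classify_polarity(regions$n_dup, regions$n_del, 0)
pol_mir <- classify_polarity(regions$n_dup, regions$n_del, 0.10)
cat("Recurrent regions:", nrow(regions), "\n")
cat("  pure under the strict gene rule: ",
    sum(pol_gene$polarity != "mixed"), "\n")
cat("  pure under the 10% miRNA mixture rule:",
    sum(pol_mir$polarity != "mixed"), "\n")

## histology-differential ANOVA on the segmented dataset
segments_list <- lapply(cohort$profiles, function(pf)
  segment_profile(pf, seed = derive_seed(seed, paste0("seg_", pf$subject))))
rm_mat <- region_mean_matrix(cohort$profiles, segments_list, regions)
anova_res <- anova_differential_regions(rm_mat, cohort$labels,
                                        fdr_threshold = 1e-5)
cat("Differential regions at FDR < 1e-5:", sum(anova_res$significant),
    "of", nrow(regions), "\n")

freqs <- region_state_frequencies(regions, cohort$labels)
sig <- which(anova_res$significant)
clusters <- merge_into_clusters(regions[sig, , drop = FALSE],
                                freqs[sig, , drop = FALSE], tolerance = 1)
cat("Merged into", nrow(clusters), "clusters (1% frequency tolerance)\n")

out <- cbind(regions[, c("chrom", "start", "end", "n_altered", "n_dup",
                         "n_del", "recurrence")],
             polarity_gene = pol_gene$polarity,
             polarity_mirna = pol_mir$polarity,
             anova_res)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/recurrent_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clusters[, c("chrom", "start", "end", "n_regions")],
            "results/differential_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("written results/recurrent_regions.tsv, results/differential_clusters.tsv\n")
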