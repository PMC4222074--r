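#!/usr/bin/env Rscript
# Step 5 — histology-predictive validation.
#
# Scores each final driver's expression as an AC-vs-SCC classifier with
# a Monte-Carlo null of 1000 random genes, builds the 15-gene
# L1-penalized histology signature with pooled 10-fold cross-validated
# AUC, and tests it against 1000 random 15-gene signatures.

suppressPackageStartupMessages(library(cnadrivers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cohort <- read_cohort("results/cohort")
report <- jsonlite::read_json("results/driver_search/report.json",
                              simplifyVector = TRUE)
acscc <- names(cohort$labels)[cohort$labels %in% c("AC", "SCC")]
expr <- cohort$expr[, acscc]
labels <- factor(cohort$labels[acscc], levels = c("AC", "SCC"))

cat("Per-driver AUC (AC vs SCC), Monte-Carlo null of 1000 random genes:\n")
val <- do.call(rbind, lapply(report$final_drivers$feature, function(f) {
  res <- single_feature_auc_test(expr, f, labels, n_draws = 1000,
                                 seed = derive_seed(seed, paste0("val_", f)))
  data.frame(feature = f, auc = res$auc, p_value = res$p_value)
}))
print(val)

sig <- l1_signature(expr, labels, signature_size = 15, cv_folds = 10,
                    seed = derive_seed(seed, "signature"))
cat("15-gene signature: cross-validated AUC",
    sprintf("%.3f", sig$cv_auc), "\n")
cat("  genes:", paste(sig$signature, collapse = ", "), "\n")
mc <- monte_carlo_signature_pvalue(expr, labels, signature_size = 15,
                                   n_draws = 1000,
                                   seed = derive_seed(seed, "signature_mc"),
                                   observed_auc = sig$cv_auc, cv_folds = 10)
cat("  Monte-Carlo null of 1000 random 15-gene signatures: median AUC",
    sprintf("%.3f", mc$null_median), ", p =",
    format(mc$p_value, digits = 3), "\n")

write.table(val, "results/driver_validation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(signature = sig$signature, cv_auc = sig$cv_auc,
       mc_null_median = mc$null_median, mc_p = mc$p_value, seed = seed),
  "results/signature.json", auto_unbox = TRUE, digits = NA)
cat("written results/driver_validation.tsv, results/signature.json\n")
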