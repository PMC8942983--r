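#!/usr/bin/env Rscript
# Stage 8: qPCR relative quantification — 2^-ddCt folds for a simulated
# case/control Ct table and the equal-variance Student's t comparison.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))
dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

ct <- simulate_ct_table(fold_change = 4, seed = seed)
folds <- delta_delta_ct(ct)
write.table(folds, file.path(run_dir, "pcr_folds.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- compare_groups(folds$fold[folds$condition == "case"],
                      folds$fold[folds$condition == "control"])
cat(sprintf("case fold: %.2f +/- %.2f; control: %.2f +/- %.2f\n",
            cmp$mean_case, cmp$sd_case, cmp$mean_control, cmp$sd_control))
cat(sprintf("Student's t = %.2f (df = %d), p = %.3g\n",
            cmp$t, cmp$df, cmp$pvalue))
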