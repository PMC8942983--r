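#!/usr/bin/env Rscript
# Stage 2: differential-expression screening at |log2FC| > 1 and
# adjusted p < 0.05 (both strict), with the per-class up/down composition.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

mat <- read_counts(file.path(run_dir, "counts.tsv"),
                   file.path(run_dir, "counts_classes.tsv"),
                   file.path(run_dir, "counts_groups.tsv"))
de <- test_differential(mat)
de_sc <- screen_de(de)
write_de_table(de, file.path(run_dir, "de_all.tsv"))
write_de_table(de_sc, file.path(run_dir, "de_screened.tsv"))

comp <- summarize_directions(de_sc)
write.table(comp, file.path(run_dir, "de_composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("screened %d of %d genes as differentially expressed\n",
            nrow(de_sc), nrow(de)))
for (i in seq_len(nrow(comp)))
  cat(sprintf("  %-6s: %d total, %d up (%s%%)\n", comp$rna_class[i],
              comp$n_total[i], comp$n_up[i],
              format(comp$pct_up[i], nsmall = 2)))
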