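#!/usr/bin/env Rscript
# Stage 7: Kaplan-Meier / log-rank prognostic screening of the key
# lncRNAs and the network mRNAs (median expression split).

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

mat <- read_counts(file.path(run_dir, "counts.tsv"),
                   file.path(run_dir, "counts_classes.tsv"),
                   file.path(run_dir, "counts_groups.tsv"))
clin <- read_clinical(file.path(run_dir, "clinical.tsv"))
keys <- readLines(file.path(run_dir, "key_lncrnas.txt"))
triplets <- read_triplets(file.path(run_dir, "triplets.tsv"))

genes <- unique(c(keys, triplets$mrna))
res <- screen_prognostic(mat, clin, genes)
write.table(res, file.path(run_dir, "prognostic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(run_dir, "truth_prognostic.tsv"),
                    stringsAsFactors = FALSE)
flagged <- res$gene_id[res$flagged & !is.na(res$pvalue)]
cat(sprintf("screened %d genes; %d flagged at log-rank p < 0.05\n",
            nrow(res), length(flagged)))
cat(sprintf("planted prognostic genes recovered: %d/%d\n",
            length(intersect(flagged, truth$gene)), nrow(truth)))
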