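#!/usr/bin/env Rscript
# Stage 6: hypergeometric over-representation of the network mRNAs
# against the gene-set collection, with all assayed mRNAs as background.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

triplets <- read_triplets(file.path(run_dir, "triplets.tsv"))
de <- read_de_table(file.path(run_dir, "de_all.tsv"))
gs <- read_gmt(file.path(run_dir, "gene_sets.gmt"))

query <- unique(triplets$mrna)
universe <- de$gene_id[de$rna_class == "mRNA"]
res <- enrich(query, gs, universe)
write.table(res, file.path(run_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("tested %d sets with overlap; %d significant at raw p < 0.05\n",
            nrow(res), sum(res$significant)))
print(head(res[, c("set_id", "k", "K", "pvalue", "adj_pvalue")], 5))
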