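#!/usr/bin/env Rscript
# Stage 5: topological ranking — node degrees, hub nodes (degree > 5),
# first/secondary relationship pairs per lncRNA, key-lncRNA selection and
# per-key sub-network extraction.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

triplets <- read_triplets(file.path(run_dir, "triplets.tsv"))
de_sc <- read_de_table(file.path(run_dir, "de_screened.tsv"))
dir <- setNames(de_sc$direction, de_sc$gene_id)
triplets$lnc_direction <- unname(dir[triplets$lncrna])
triplets$mirna_direction <- unname(dir[triplets$mirna])
triplets$mrna_direction <- unname(dir[triplets$mrna])

nets <- build_network(triplets)
pooled <- pool_networks(nets)

ranking <- rank_lncrnas(pooled)
write.table(ranking, file.path(run_dir, "topology.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
keys <- select_key_lncrnas(ranking, k = 3)
writeLines(keys, file.path(run_dir, "key_lncrnas.txt"))

hubs <- hub_nodes(pooled, threshold = 5)
write.table(hubs, file.path(run_dir, "hubs_pooled.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (k in keys) {
  sub <- extract_subnetwork(pooled, k)
  if (nrow(sub$edges) > 0)
    write_network(sub, file.path(run_dir, sprintf("subnetwork_%s.sif", k)),
                  "sif")
}

cat(sprintf("ranked %d lncRNAs; %d hub nodes (degree > 5); key lncRNAs: %s\n",
            nrow(ranking), nrow(hubs), paste(keys, collapse = ", ")))
print(head(ranking, 10))
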