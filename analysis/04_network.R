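#!/usr/bin/env Rscript
# Stage 4: assemble direction-opposed competing triplets and build the
# lncRNA-up and lncRNA-down group networks; export for Cytoscape.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

de_sc <- read_de_table(file.path(run_dir, "de_screened.tsv"))
mm <- read.delim(file.path(run_dir, "edges_mirna_mrna.tsv"),
                 stringsAsFactors = FALSE)
ml <- read.delim(file.path(run_dir, "edges_mirna_lnc.tsv"),
                 stringsAsFactors = FALSE)
edges <- consensus_edges(mm, ml)

pairs <- build_pairs(de_sc, edges)
triplets <- assemble_triplets(pairs)
write_triplets(triplets, file.path(run_dir, "triplets.tsv"))
nets <- build_network(triplets)
for (g in names(nets)) {
  if (nrow(nets[[g]]$edges) == 0) next
  write_network(nets[[g]], file.path(run_dir, sprintf("network_%s.sif", g)),
                "sif")
  write_network(nets[[g]],
                file.path(run_dir, sprintf("network_%s.graphml", g)),
                "graphml")
}

# score against the planted ground truth
truth <- read_triplets(file.path(run_dir, "truth_triplets.tsv"))
found <- paste(triplets$lncrna, triplets$mirna, triplets$mrna)
planted <- paste(truth$lncrna, truth$mirna, truth$mrna)
cat(sprintf("assembled %d competing triplets; recovered %d/%d planted, %d spurious\n",
            nrow(triplets), length(intersect(found, planted)),
            length(planted), length(setdiff(found, planted))))
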