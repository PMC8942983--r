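#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — two-group NB counts for
# the three RNA classes with planted competing triplets, multi-database
# target tables with decoys, clinical survival, and a gene-set collection.
# Everything downstream reads only the files written here.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))
dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_counts(cfg)
tabs <- simulate_interactions(sim$truth, cfg)
clin <- simulate_survival(sim$matrix, sim$truth, cfg)

write_counts(sim$matrix, file.path(run_dir, "counts"))
for (db in names(tabs))
  write_interactions(tabs[[db]],
                     file.path(run_dir, sprintf("targets_%s.tsv", db)),
                     with_score = db == cfg$score_db)
write_clinical(clin, file.path(run_dir, "clinical.tsv"))

universe <- rownames(sim$matrix$counts)[sim$matrix$rna_class == "mRNA"]
gs <- simulate_gene_sets(sim$truth, universe, seed = cfg$seed)
write_gmt(gs, file.path(run_dir, "gene_sets.gmt"))

# ground truth, for recovery scoring at the end of the workflow
write_triplets(sim$truth$planted_triplets,
               file.path(run_dir, "truth_triplets.tsv"))
write.table(data.frame(gene = names(sim$truth$planted_de),
                       direction = sim$truth$planted_de),
            file.path(run_dir, "truth_de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(sim$truth$prognostic),
                       hazard_log_ratio = sim$truth$prognostic),
            file.path(run_dir, "truth_prognostic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d genes x %d samples (seed %d): %d planted triplets, %d decoy mRNA edges, %d prognostic genes\n",
  nrow(sim$matrix$counts), ncol(sim$matrix$counts), seed,
  nrow(sim$truth$planted_triplets), cfg$decoy_edges,
  length(sim$truth$prognostic)))
cat("inputs written to", run_dir, "\n")
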