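#!/usr/bin/env Rscript
# Stage 3: miRNA-target consensus — score-filter the TargetScan-style
# table at score < -0.1, keep miRNA-mRNA pairs in >= 2 databases, and
# pass the single-source miRNA-lncRNA table through deduplication.

suppressMessages(library(cernakit))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
run_dir <- file.path("results", sprintf("run_seed%d", seed))

cfg <- simulation_config(seed = seed)  # db naming only
plain_dbs <- setdiff(cfg$db_names, cfg$score_db)
tabs <- lapply(plain_dbs, function(db)
  read_interactions(file.path(run_dir, sprintf("targets_%s.tsv", db)), db))
ts_raw <- read_interactions(
  file.path(run_dir, sprintf("targets_%s.tsv", cfg$score_db)),
  cfg$score_db)
ts <- filter_targetscan(ts_raw)
cat(sprintf("score filter: %d of %d %s records kept (score < -0.1)\n",
            nrow(ts), nrow(ts_raw), cfg$score_db))

cons <- consensus_mrna_targets(c(tabs, list(ts)))
lnc <- lncrna_targets(read_interactions(
  file.path(run_dir, sprintf("targets_%s.tsv", cfg$lnc_db)),
  cfg$lnc_db, target_class = "lncRNA"))

write.table(cons, file.path(run_dir, "edges_mirna_mrna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(lnc, file.path(run_dir, "edges_mirna_lnc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "consensus: %d miRNA-mRNA edges (>= 2 databases), %d miRNA-lncRNA edges\n",
  nrow(cons), nrow(lnc)))
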