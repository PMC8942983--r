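# Fixture builders and brute-force oracles shared across the suite.
# Oracles are deliberately naive (nested loops, exhaustive enumeration)
# and never call the code paths they check.

# The published top-10 lncRNA topology rows: gene, lnc-miRNA pairs
# (= node degree), mi-mRNA pairs, total.
table1_rows <- function() {
  data.frame(
    id = c("XIST", "TUG1", "GABPB1-AS1", "MIRLET7BHG", "AC092127.1",
           "SNHG1", "NEAT1", "SNHG3", "H19", "AC074117.1"),
    first = c(20, 10, 10, 7, 6, 6, 5, 5, 5, 5),
    secondary = c(38, 23, 13, 11, 12, 9, 11, 9, 9, 9),
    stringsAsFactors = FALSE)
}

# Build a network shaped to the printed pair counts: each lncRNA gets
# `first` private miRNA partners; its miRNAs carry `secondary` distinct
# mRNA edges in total (each miRNA at least one, the first miRNA takes the
# surplus). All lncRNAs upregulated, so everything lands in one group.
make_table1_network <- function() {
  rows <- table1_rows()
  tri <- list()
  for (r in seq_len(nrow(rows))) {
    lnc <- rows$id[r]
    f <- rows$first[r]
    s <- rows$secondary[r]
    mirs <- sprintf("mir-%02d-%02d", r, seq_len(f))
    per_mir <- rep(1L, f)
    per_mir[1] <- per_mir[1] + (s - f)
    for (j in seq_len(f)) {
      mrnas <- sprintf("gene-%02d-%02d-%02d", r, j, seq_len(per_mir[j]))
      tri[[length(tri) + 1]] <- data.frame(
        lncrna = lnc, mirna = mirs[j], mrna = mrnas,
        lnc_direction = "up", mirna_direction = "down",
        mrna_direction = "up", group = "lnc_up",
        stringsAsFactors = FALSE)
    }
  }
  cerna_network(do.call(rbind, tri), "lnc_up")
}

# random but direction-consistent triplet set over small id pools
random_triplets <- function(n_lnc = 6, n_mir = 4, n_mrna = 8,
                            n_pick = 15, seed = 1) {
  set.seed(seed)
  lnc <- sprintf("L%02d", seq_len(n_lnc))
  mir <- sprintf("M%02d", seq_len(n_mir))
  mrna <- sprintf("G%02d", seq_len(n_mrna))
  dir <- c(stats::setNames(sample(c("up", "down"), n_lnc, TRUE), lnc),
           stats::setNames(sample(c("up", "down"), n_mir, TRUE), mir),
           stats::setNames(sample(c("up", "down"), n_mrna, TRUE), mrna))
  cand <- expand.grid(lncrna = lnc, mirna = mir, mrna = mrna,
                      stringsAsFactors = FALSE)
  ok <- dir[cand$lncrna] == dir[cand$mrna] &
    dir[cand$lncrna] != dir[cand$mirna]
  cand <- cand[ok, , drop = FALSE]
  cand <- cand[sample(nrow(cand), min(n_pick, nrow(cand))), , drop = FALSE]
  cand$lnc_direction <- unname(dir[cand$lncrna])
  cand$mirna_direction <- unname(dir[cand$mirna])
  cand$mrna_direction <- unname(dir[cand$mrna])
  cand$group <- ifelse(cand$lnc_direction == "up", "lnc_up", "lnc_down")
  rownames(cand) <- NULL
  cand
}

# adjacency-matrix degree oracle (independent of the edges bookkeeping)
oracle_degrees <- function(net) {
  ids <- net$nodes$id
  adj <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    adj[net$edges$from[i], net$edges$to[i]] <- 1L
    adj[net$edges$to[i], net$edges$from[i]] <- 1L
  }
  rowSums(adj)
}

# recompute pair counts straight from the triplet table
oracle_count_pairs <- function(net, lnc) {
  tri <- net$triplets
  mis <- unique(tri$mirna[tri$lncrna == lnc])
  sec <- nrow(unique(tri[tri$mirna %in% mis, c("mirna", "mrna")]))
  c(first = length(mis), secondary = sec, total = length(mis) + sec)
}

# nested-loop join oracle for triplet assembly
oracle_triplet_join <- function(lnc_mi, mi_mrna) {
  out <- character(0)
  for (i in seq_len(nrow(lnc_mi)))
    for (j in seq_len(nrow(mi_mrna)))
      if (lnc_mi$mirna[i] == mi_mrna$mirna[j])
        out <- c(out, paste(lnc_mi$lncrna[i], lnc_mi$mirna[i],
                            mi_mrna$mrna[j]))
  sort(unique(out))
}

# exhaustive hypergeometric upper tail
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-pair support-count oracle for the database consensus
oracle_consensus <- function(tables, min_db = 2) {
  rec <- do.call(rbind, tables)
  rec <- rec[rec$target_class == "mRNA", ]
  pairs <- unique(rec[, c("mirna", "target")])
  keep <- character(0)
  for (i in seq_len(nrow(pairs))) {
    dbs <- unique(rec$source_db[rec$mirna == pairs$mirna[i] &
                                rec$target == pairs$target[i]])
    if (length(dbs) >= min_db)
      keep <- c(keep, paste(pairs$mirna[i], pairs$target[i]))
  }
  sort(keep)
}

# small interaction-record constructor for target_consensus tests
irec <- function(mirna, target, db, score = NA_real_,
                 target_class = "mRNA") {
  data.frame(mirna = mirna, target = target, target_class = target_class,
             source_db = db, score = score, stringsAsFactors = FALSE)
}
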