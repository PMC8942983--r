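de_row <- function(gene, cl, dir) {
  data.frame(gene_id = gene, rna_class = cl,
             log2fc = ifelse(dir == "up", 2, -2), pvalue = 0.001,
             adj_pvalue = 0.01, direction = dir, stringsAsFactors = FALSE)
}

test_that("pair building enforces opposite DE directions", {
  de <- rbind(de_row("L1", "lncRNA", "up"), de_row("L2", "lncRNA", "up"),
              de_row("M1", "miRNA", "down"), de_row("M2", "miRNA", "up"),
              de_row("G1", "mRNA", "up"))
  edges <- consensus_edges(
    mirna_mrna = data.frame(mirna = c("M1", "M2"), mrna = "G1",
                            n_db = 2L, dbs = "a,b",
                            stringsAsFactors = FALSE),
    mirna_lnc = data.frame(mirna = c("M1", "M2", "M1"),
                           lncrna = c("L1", "L2", "L9"),
                           stringsAsFactors = FALSE))
  expect_message(pairs <- build_pairs(de, edges), "dropped")
  # (M1,L1): opposite, kept; (M2,L2): both up, rejected; L9 not in DE
  expect_equal(pairs$lnc_mi$lncrna, "L1")
  expect_equal(pairs$lnc_mi$mirna, "M1")
  # (M1,G1) opposite kept; (M2,G1) both up rejected
  expect_equal(pairs$mi_mrna$mirna, "M1")

  # brute-force direction check over a 4-edge fixture
  dirs <- c(L1 = "up", L2 = "down", M1 = "down", M2 = "up",
            G1 = "up", G2 = "down")
  de4 <- rbind(de_row("L1", "lncRNA", "up"), de_row("L2", "lncRNA", "down"),
               de_row("M1", "miRNA", "down"), de_row("M2", "miRNA", "up"),
               de_row("G1", "mRNA", "up"), de_row("G2", "mRNA", "down"))
  e4 <- consensus_edges(
    mirna_mrna = data.frame(mirna = c("M1", "M1", "M2", "M2"),
                            mrna = c("G1", "G2", "G1", "G2"),
                            n_db = 2L, dbs = "a,b",
                            stringsAsFactors = FALSE),
    mirna_lnc = data.frame(mirna = character(), lncrna = character(),
                           stringsAsFactors = FALSE))
  kept <- build_pairs(de4, e4)$mi_mrna
  manual <- c("M1 G1", "M2 G2")  # the only direction-opposed pairs
  expect_setequal(paste(kept$mirna, kept$mrna), manual)
})

test_that("triplet assembly equals the nested-loop join oracle", {
  # trivial join and no-shared-miRNA cases
  lnc_mi <- data.frame(lncrna = "L1", mirna = "M1", lnc_direction = "up",
                       mirna_direction = "down", stringsAsFactors = FALSE)
  mi_mrna <- data.frame(mirna = "M1", mrna = "G1", mirna_direction = "down",
                        mrna_direction = "up", stringsAsFactors = FALSE)
  tri <- assemble_triplets(list(lnc_mi = lnc_mi, mi_mrna = mi_mrna))
  expect_equal(nrow(tri), 1)
  expect_equal(tri$group, "lnc_up")

  mi_other <- mi_mrna; mi_other$mirna <- "M2"
  expect_equal(nrow(assemble_triplets(list(lnc_mi = lnc_mi,
                                           mi_mrna = mi_other))), 0)

  # 3 lncRNAs x 2 miRNAs x 4 mRNAs toy with 5 + 6 pairs
  lnc_mi5 <- data.frame(
    lncrna = c("L1", "L1", "L2", "L3", "L3"),
    mirna = c("M1", "M2", "M1", "M1", "M2"),
    lnc_direction = "up", mirna_direction = "down",
    stringsAsFactors = FALSE)
  mi_mrna6 <- data.frame(
    mirna = c("M1", "M1", "M1", "M2", "M2", "M2"),
    mrna = c("G1", "G2", "G3", "G2", "G3", "G4"),
    mirna_direction = "down", mrna_direction = "up",
    stringsAsFactors = FALSE)
  tri2 <- assemble_triplets(list(lnc_mi = lnc_mi5, mi_mrna = mi_mrna6))
  expect_identical(paste(tri2$lncrna, tri2$mirna, tri2$mrna),
                   oracle_triplet_join(lnc_mi5, mi_mrna6))

  # direction violations are caught on construction
  bad <- lnc_mi; bad$lnc_direction <- "down"
  expect_error(assemble_triplets(list(lnc_mi = bad, mi_mrna = mi_mrna)),
               "direction constraint")
})

test_that("network construction collapses multiplicity and stays tripartite", {
  tri1 <- data.frame(lncrna = "L1", mirna = "M1", mrna = "G1",
                     lnc_direction = "up", mirna_direction = "down",
                     mrna_direction = "up", group = "lnc_up",
                     stringsAsFactors = FALSE)
  nets <- suppressMessages(build_network(tri1))
  expect_equal(nrow(nets$lnc_up$nodes), 3)
  expect_equal(nrow(nets$lnc_up$edges), 2)
  expect_equal(nrow(nets$lnc_down$nodes), 0)

  # two triplets sharing miRNA and mRNA: 4 nodes, 3 edges, shared edge x2
  tri2 <- rbind(tri1, within(tri1, lncrna <- "L2"))
  net2 <- suppressMessages(build_network(tri2))$lnc_up
  expect_equal(nrow(net2$nodes), 4)
  expect_equal(nrow(net2$edges), 3)
  shared <- net2$edges[net2$edges$edge_type == "miRNA-mRNA", ]
  expect_equal(shared$n_triplets, 2L)

  empty <- suppressMessages(build_network(tri1[0, ]))
  expect_equal(nrow(empty$lnc_up$nodes), 0)
  expect_equal(nrow(empty$lnc_down$edges), 0)
})

test_that("random direction-consistent triplet sets build valid partitioned networks", {
  for (s in 1:5) {
    tri <- random_triplets(n_pick = 20, seed = s)
    nets <- suppressMessages(build_network(tri))
    for (net in nets) expect_silent(validate_tripartite(net))
    # groups partition the triplets by lncRNA direction
    expect_equal(nrow(nets$lnc_up$triplets) + nrow(nets$lnc_down$triplets),
                 nrow(unique(tri)))
    expect_true(all(nets$lnc_up$triplets$lnc_direction == "up"))
    expect_true(all(nets$lnc_down$triplets$lnc_direction == "down"))
    # edge set equals the union of per-triplet 2-edge paths
    for (net in nets) {
      want <- unique(c(paste(net$triplets$lncrna, net$triplets$mirna),
                       paste(net$triplets$mirna, net$triplets$mrna)))
      expect_setequal(paste(net$edges$from, net$edges$to), want)
    }
  }
})

test_that("optional correlation filter tightens pair sets on same-cohort data", {
  de <- rbind(de_row("L1", "lncRNA", "up"), de_row("M1", "miRNA", "down"),
              de_row("G1", "mRNA", "up"), de_row("G2", "mRNA", "up"))
  edges <- consensus_edges(
    mirna_mrna = data.frame(mirna = "M1", mrna = c("G1", "G2"),
                            n_db = 2L, dbs = "a,b",
                            stringsAsFactors = FALSE),
    mirna_lnc = data.frame(mirna = "M1", lncrna = "L1",
                           stringsAsFactors = FALSE))
  expr <- rbind(L1 = c(1, 2, 3, 4, 5, 6),
                M1 = c(6, 5, 4, 3, 2, 1),   # anti-correlated with L1, G1
                G1 = c(1, 2, 3, 4, 5, 7),
                G2 = c(2, 1, 2, 1, 2, 1))   # uncorrelated with M1
  colnames(expr) <- sprintf("s%d", 1:6)
  with_cor <- build_pairs(de, edges, cor_matrix = expr)
  expect_equal(with_cor$mi_mrna$mrna, "G1")
  expect_equal(with_cor$lnc_mi$lncrna, "L1")
  without <- build_pairs(de, edges)
  expect_equal(nrow(without$mi_mrna), 2)
})
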