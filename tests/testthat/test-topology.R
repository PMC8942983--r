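test_that("degrees match the adjacency-matrix and igraph oracles", {
  tri1 <- data.frame(lncrna = "L1", mirna = "M1", mrna = "G1",
                     lnc_direction = "up", mirna_direction = "down",
                     mrna_direction = "up", group = "lnc_up",
                     stringsAsFactors = FALSE)
  net1 <- cerna_network(tri1, "lnc_up")
  deg1 <- node_degrees(net1)
  expect_equal(unname(deg1[c("L1", "M1", "G1")]), c(1L, 2L, 1L))

  # star: one miRNA with 6 lncRNA partners (each with a private mRNA)
  star <- do.call(rbind, lapply(1:6, function(i)
    data.frame(lncrna = sprintf("L%d", i), mirna = "M1",
               mrna = sprintf("G%d", i), lnc_direction = "up",
               mirna_direction = "down", mrna_direction = "up",
               group = "lnc_up", stringsAsFactors = FALSE)))
  deg_star <- node_degrees(cerna_network(star, "lnc_up"))
  expect_equal(unname(deg_star["M1"]), 12L)  # 6 lncRNA + 6 mRNA edges
  expect_true(all(deg_star[paste0("L", 1:6)] == 1L))

  # random networks: adjacency row sums and igraph agree
  for (s in 1:5) {
    net <- cerna_network(random_triplets(n_pick = 30, seed = s), "any")
    deg <- node_degrees(net)
    expect_equal(deg[net$nodes$id], oracle_degrees(net))
    ig <- igraph::degree(as_igraph(net))
    expect_equal(deg[names(ig)], ig[names(ig)], ignore_attr = TRUE)
  }
})

test_that("hub calling is strict at the threshold", {
  net <- make_table1_network()
  hubs <- hub_nodes(net, threshold = 5)
  deg <- node_degrees(net)
  expect_setequal(hubs$id, names(deg)[deg > 5])
  expect_false(any(hubs$degree == 5))
  # XIST (degree 20) is a hub; a degree-5 lncRNA (NEAT1) is not
  expect_true("XIST" %in% hubs$id)
  expect_false("NEAT1" %in% hubs$id)
  expect_equal(nrow(hub_nodes(net, threshold = Inf)), 0)
  expect_equal(nrow(hub_nodes(net, threshold = -1)), nrow(net$nodes))
  empty <- cerna_network(net$triplets[0, ], "lnc_up")
  expect_equal(nrow(hub_nodes(empty)), 0)
})

test_that("pair counting reproduces all printed topology rows", {
  net <- make_table1_network()
  rows <- table1_rows()
  for (r in seq_len(nrow(rows))) {
    rec <- count_pairs(net, rows$id[r])
    expect_equal(rec$node_degree, rows$first[r])
    expect_equal(rec$first_pairs, rows$first[r])
    expect_equal(rec$secondary_pairs, rows$secondary[r])
    expect_equal(rec$total_pairs, rows$first[r] + rows$secondary[r])
  }
  expect_error(count_pairs(net, "nonexistent"), "unknown node")
  expect_error(count_pairs(net, "mir-01-01"), "not an lncRNA")
})

test_that("pair counts on random networks match the triplet-table oracle", {
  for (s in 1:6) {
    net <- cerna_network(random_triplets(n_pick = 25, seed = s + 100),
                         "any")
    lncs <- net$nodes$id[net$nodes$rna_class == "lncRNA"]
    for (l in lncs) {
      rec <- count_pairs(net, l)
      want <- oracle_count_pairs(net, l)
      expect_equal(rec$first_pairs, unname(want["first"]))
      expect_equal(rec$secondary_pairs, unname(want["secondary"]))
      expect_equal(rec$total_pairs, unname(want["total"]))
      expect_equal(rec$node_degree, rec$first_pairs)
      expect_equal(rec$total_pairs, rec$first_pairs + rec$secondary_pairs)
    }
  }
})

test_that("ranking and key selection follow degree-then-total with id tie-break", {
  net <- make_table1_network()
  ranked <- rank_lncrnas(net)
  expect_equal(ranked$lncrna_id[1:3], c("XIST", "TUG1", "GABPB1-AS1"))
  # TUG1 over GABPB1-AS1 despite tied degree 10: totals 33 vs 23
  expect_equal(ranked$node_degree[2:3], c(10, 10))
  expect_true(ranked$total_pairs[2] > ranked$total_pairs[3])

  keys <- select_key_lncrnas(ranked, k = 3)
  expect_setequal(keys, c("XIST", "TUG1", "GABPB1-AS1"))
  expect_identical(select_key_lncrnas(ranked, k = 100),
                   ranked$lncrna_id)

  # all-equal stats fall back to lexicographic order
  flat <- cerna_network(do.call(rbind, lapply(c("B", "A", "C"), function(l)
    data.frame(lncrna = l, mirna = paste0("M", l), mrna = paste0("G", l),
               lnc_direction = "up", mirna_direction = "down",
               mrna_direction = "up", group = "lnc_up",
               stringsAsFactors = FALSE))), "lnc_up")
  expect_equal(rank_lncrnas(flat)$lncrna_id, c("A", "B", "C"))

  # disjoint top-k sets yield an empty selection with a warning:
  # L1 dominates degree, L2 dominates totals
  mixed <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      data.frame(lncrna = "L1", mirna = sprintf("MA%d", i), mrna = "GA",
                 lnc_direction = "up", mirna_direction = "down",
                 mrna_direction = "up", group = "lnc_up",
                 stringsAsFactors = FALSE))),
    do.call(rbind, lapply(1:9, function(i)
      data.frame(lncrna = "L2", mirna = "MB", mrna = sprintf("GB%d", i),
                 lnc_direction = "up", mirna_direction = "down",
                 mrna_direction = "up", group = "lnc_up",
                 stringsAsFactors = FALSE))))
  ranked_mixed <- rank_lncrnas(cerna_network(mixed, "lnc_up"))
  expect_warning(none <- select_key_lncrnas(ranked_mixed, k = 1),
                 "disjoint")
  expect_length(none, 0)
})

test_that("sub-network extraction is an idempotent tripartite restriction", {
  net <- make_table1_network()
  sub <- extract_subnetwork(net, "XIST")
  expect_silent(validate_tripartite(sub))
  # 1 lncRNA + 20 miRNAs + its distinct mRNAs
  n_mrna <- sum(sub$nodes$rna_class == "mRNA")
  expect_equal(nrow(sub$nodes), 1 + 20 + n_mrna)
  expect_equal(sum(sub$nodes$rna_class == "miRNA"), 20)
  # oracle: union of the triplets through XIST
  tri <- net$triplets[net$triplets$lncrna == "XIST", ]
  expect_setequal(sub$nodes$id,
                  unique(c("XIST", tri$mirna, tri$mrna)))
  expect_true(all(paste(sub$edges$from, sub$edges$to) %in%
                  paste(net$edges$from, net$edges$to)))
  # idempotent
  sub2 <- extract_subnetwork(sub, "XIST")
  expect_equal(sub2$nodes, sub$nodes)
  expect_equal(sub2$edges, sub$edges)
  expect_error(extract_subnetwork(net, "mir-01-01"), "not an lncRNA")
})

test_that("pooling group networks sums support and preserves structure", {
  tri <- random_triplets(n_pick = 20, seed = 9)
  nets <- suppressMessages(build_network(tri))
  pooled <- pool_networks(nets)
  expect_silent(validate_tripartite(pooled))
  expect_equal(nrow(pooled$triplets),
               nrow(nets$lnc_up$triplets) + nrow(nets$lnc_down$triplets))
  # a pooled hub set can only grow relative to each group
  hp <- hub_nodes(pooled, 1)
  for (g in names(nets)) {
    hg <- hub_nodes(nets[[g]], 1)
    expect_true(all(hg$id %in% hp$id))
  }
})
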