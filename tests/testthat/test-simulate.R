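test_that("simulation is deterministic and validates its config", {
  cfg <- simulation_config(seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  ta <- simulate_interactions(a$truth, cfg)
  tb <- simulate_interactions(b$truth, cfg)
  expect_identical(ta, tb)
  sa <- simulate_survival(a$matrix, a$truth, cfg)
  expect_identical(sa, simulate_survival(b$matrix, b$truth, cfg))

  expect_error(simulation_config(n_triplets = 50, n_mirna = 10),
               "infeasible")
  expect_error(simulation_config(db_support = c("1" = 1)), "db_support")
  expect_error(simulation_config(n_case = 0), "sizes")
})

test_that("planted triplets are direction-consistent and fully supported", {
  for (s in c(3, 17)) {
    cfg <- simulation_config(n_triplets = 8, seed = s)
    sim <- simulate_counts(cfg)
    tri <- sim$truth$planted_triplets
    expect_equal(nrow(tri), 8)
    expect_true(all(tri$lnc_direction == tri$mrna_direction))
    expect_true(all(tri$lnc_direction != tri$mirna_direction))

    tabs <- simulate_interactions(sim$truth, cfg)
    merged <- do.call(rbind, tabs[cfg$db_names])
    for (i in seq_len(nrow(tri))) {
      dbs <- unique(merged$source_db[merged$mirna == tri$mirna[i] &
                                     merged$target == tri$mrna[i]])
      expect_gte(length(dbs), 2)
    }
    # score-bearing true records always pass the score filter
    ts <- tabs[[cfg$score_db]]
    true_key <- paste(tri$mirna, tri$mrna)
    true_in_ts <- ts[paste(ts$mirna, ts$target) %in% true_key, ]
    expect_true(all(true_in_ts$score < -0.1))
    # every planted miRNA-lncRNA edge is in the single-source table
    lnc_tab <- tabs[[cfg$lnc_db]]
    expect_true(all(paste(tri$mirna, tri$lncrna) %in%
                    paste(lnc_tab$mirna, lnc_tab$target)))
  }
})

test_that("decoy edges are single-database and removed by consensus", {
  cfg <- simulation_config(decoy_edges = 40, decoy_lnc_edges = 0, seed = 5)
  sim <- simulate_counts(cfg)
  tabs <- simulate_interactions(sim$truth, cfg)
  merged <- do.call(rbind, tabs[cfg$db_names])
  true_key <- with(subset(sim$truth$true_edges, target_class == "mRNA"),
                   paste(mirna, target))
  key <- paste(merged$mirna, merged$target)
  decoy_support <- table(key[!key %in% true_key])
  expect_true(all(decoy_support == 1))
  # half of the score-bearing decoys fall at/above the score cut
  ts <- tabs[[cfg$score_db]]
  decoy_scores <- ts$score[!paste(ts$mirna, ts$target) %in% true_key]
  if (length(decoy_scores) > 1)
    expect_equal(sum(decoy_scores >= -0.1),
                 floor(length(decoy_scores) / 2) +
                   length(decoy_scores) %% 2)
  cons <- consensus_mrna_targets(c(tabs[setdiff(cfg$db_names,
                                                cfg$score_db)],
                                   list(filter_targetscan(ts))))
  expect_true(all(paste(cons$mirna, cons$mrna) %in% true_key))
})

test_that("zero decoys: consensus recovers exactly the true mRNA edges", {
  cfg <- simulation_config(n_lnc = 60, n_mirna = 50, n_mrna = 80,
                           n_triplets = 50, decoy_edges = 0,
                           decoy_lnc_edges = 0, seed = 23)
  sim <- simulate_counts(cfg)
  tabs <- simulate_interactions(sim$truth, cfg)
  cons <- consensus_mrna_targets(
    c(tabs[setdiff(cfg$db_names, cfg$score_db)],
      list(filter_targetscan(tabs[[cfg$score_db]]))))
  true_key <- with(subset(sim$truth$true_edges, target_class == "mRNA"),
                   paste(mirna, target))
  expect_setequal(paste(cons$mirna, cons$mrna), true_key)
})

test_that("null effect size leaves screening at the nominal false-positive level", {
  cfg <- simulation_config(n_lnc = 100, n_mirna = 50, n_mrna = 150,
                           effect_log2fc = 0, seed = 31)
  sim <- simulate_counts(cfg)
  de <- test_differential(sim$matrix)
  kept <- screen_de(de)
  # BH-adjusted retention over 300 null genes should be near zero
  expect_lte(nrow(kept), ceiling(0.05 * nrow(de)))
})

test_that("survival generator needs prognostic genes and hits the censoring target", {
  cfg <- simulation_config(seed = 2, n_case = 150, n_control = 150,
                           hazard_log_ratio = 0)
  sim <- simulate_counts(cfg)
  clin <- simulate_survival(sim$matrix, sim$truth, cfg)
  expect_equal(nrow(clin), 300)
  expect_true(all(clin$time > 0))
  cens <- mean(clin$event == 0)
  expect_gt(cens, 0.15)
  expect_lt(cens, 0.45)

  no_prog <- sim$truth
  no_prog$prognostic <- numeric(0)
  expect_error(simulate_survival(sim$matrix, no_prog, cfg),
               "no prognostic genes")
})
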