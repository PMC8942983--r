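#' One-shot synthetic ceRNA pipeline
#'
#' Runs the full analysis on synthetic inputs: simulate counts and target
#' tables, screen differential expression, take the database consensus,
#' assemble direction-opposed competing triplets into the two group
#' networks, rank lncRNAs topologically and select key lncRNAs, run
#' over-representation analysis of the network mRNAs, and screen key genes
#' for prognostic value against simulated survival. All stage outputs are
#' returned and, when \code{out_dir} is given, written as TSVs; the run is
#' fully determined by \code{config$seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param out_dir optional directory for TSV artifacts (created if
#'   needed).
#' @param hub_threshold hub degree cut (strict; default 5).
#' @param top_k depth of the key-lncRNA rankings (default 3).
#' @param alpha significance level for enrichment and prognostic
#'   screening.
#' @return list with elements \code{matrix}, \code{truth}, \code{tables},
#'   \code{de}, \code{de_screened}, \code{edges}, \code{pairs},
#'   \code{triplets}, \code{networks}, \code{pooled}, \code{ranking},
#'   \code{key_lncrnas}, \code{hubs} (per group and pooled),
#'   \code{enrichment}, \code{clinical}, \code{prognostic},
#'   \code{recovery} (triplet recovery vs ground truth), \code{summary}
#'   (named counts).
#' @export
run_cerna_pipeline <- function(config = simulation_config(),
                               out_dir = NULL, hub_threshold = 5,
                               top_k = 3, alpha = 0.05) {
  sim <- simulate_counts(config)
  mat <- sim$matrix
  truth <- sim$truth
  tabs <- simulate_interactions(truth, config)

  de <- test_differential(mat)
  de_sc <- screen_de(de)

  ts_tab <- filter_targetscan(tabs[[config$score_db]])
  mrna_tabs <- tabs[setdiff(config$db_names, config$score_db)]
  mm <- consensus_mrna_targets(c(mrna_tabs, list(ts_tab)))
  ml <- lncrna_targets(tabs[[config$lnc_db]])
  edges <- consensus_edges(mm, ml)

  pairs <- build_pairs(de_sc, edges)
  triplets <- assemble_triplets(pairs)
  nets <- build_network(triplets)
  pooled <- pool_networks(nets)

  ranking <- rank_lncrnas(pooled)
  keys <- select_key_lncrnas(ranking, k = top_k)
  hubs <- list(lnc_up = hub_nodes(nets$lnc_up, hub_threshold),
               lnc_down = hub_nodes(nets$lnc_down, hub_threshold),
               pooled = hub_nodes(pooled, hub_threshold))

  # background = all assayed mRNAs; the screened list is the query's
  # superset and would degenerate to query == universe at strong effects
  universe <- de$gene_id[de$rna_class == "mRNA"]
  net_mrnas <- pooled$nodes$id[pooled$nodes$rna_class == "mRNA"]
  gene_sets <- simulate_gene_sets(truth, universe, seed = config$seed)
  enr <- enrich(net_mrnas, gene_sets, universe, alpha = alpha)

  clinical <- simulate_survival(mat, truth, config)
  surv_genes <- unique(c(keys, net_mrnas))
  prognostic <- screen_prognostic(mat, clinical, surv_genes, alpha = alpha)

  planted_key <- with(truth$planted_triplets,
                      paste(lncrna, mirna, mrna))
  found_key <- with(triplets, paste(lncrna, mirna, mrna))
  recovery <- list(
    n_planted = length(planted_key),
    n_recovered = length(intersect(planted_key, found_key)),
    n_spurious = length(setdiff(found_key, planted_key)),
    exact = setequal(planted_key, found_key))

  summary <- c(genes = nrow(mat$counts),
               samples = ncol(mat$counts),
               de_screened = nrow(de_sc),
               consensus_mrna_edges = nrow(mm),
               lnc_edges = nrow(ml),
               triplets = nrow(triplets),
               nodes_up = nrow(nets$lnc_up$nodes),
               edges_up = nrow(nets$lnc_up$edges),
               nodes_down = nrow(nets$lnc_down$nodes),
               edges_down = nrow(nets$lnc_down$edges),
               hubs_pooled = nrow(hubs$pooled),
               key_lncrnas = length(keys),
               enriched_sets = sum(enr$significant),
               prognostic_flagged = sum(prognostic$flagged,
                                        na.rm = TRUE))

  res <- list(matrix = mat, truth = truth, tables = tabs, de = de,
              de_screened = de_sc, edges = edges, pairs = pairs,
              triplets = triplets, networks = nets, pooled = pooled,
              ranking = ranking, key_lncrnas = keys, hubs = hubs,
              enrichment = enr, clinical = clinical,
              prognostic = prognostic, recovery = recovery,
              summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_counts(mat, p("counts"))
    for (db in names(tabs))
      write_interactions(tabs[[db]], p(sprintf("targets_%s.tsv", db)),
                         with_score = db == config$score_db)
    write_de_table(de, p("de_all.tsv"))
    write_de_table(de_sc, p("de_screened.tsv"))
    write_triplets(triplets, p("triplets.tsv"))
    for (g in names(nets)) {
      if (nrow(nets[[g]]$edges) > 0) {
        write_network(nets[[g]], p(sprintf("network_%s.sif", g)), "sif")
        write_network(nets[[g]], p(sprintf("network_%s.graphml", g)),
                      "graphml")
      }
    }
    utils::write.table(ranking, p("topology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(enr, p("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_clinical(clinical, p("clinical.tsv"))
    utils::write.table(prognostic, p("prognostic.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(paste(names(summary), summary, sep = "\t"),
               p("summary.tsv"))
  }
  res
}
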