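#' Configuration for the synthetic ceRNA study generator
#'
#' Defines the conditions under which all synthetic inputs are drawn:
#' two-group negative-binomial counts for three RNA classes with planted
#' direction-opposed competing triplets, multi-database target tables with
#' decoys, and survival times whose hazard depends on planted prognostic
#' genes.
#'
#' @param n_lnc,n_mirna,n_mrna number of lncRNA / miRNA / mRNA genes.
#' @param n_case,n_control samples per group.
#' @param baseline_mean median of the log-normal distribution that gene
#'   baseline means are drawn from (counts scale).
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param n_triplets number of planted competing triplets (disjoint genes).
#' @param effect_log2fc planted absolute log2 fold change for every gene in
#'   a planted triplet; 0 plants labels but no signal.
#' @param decoy_edges number of decoy miRNA-mRNA edges, each supported by
#'   exactly one database.
#' @param decoy_lnc_edges number of decoy miRNA-lncRNA edges in the
#'   single-source lncRNA-target table.
#' @param db_names names of the mRNA-target databases being emulated.
#' @param score_db which of \code{db_names} carries context scores
#'   (TargetScan-style; true edges scored below \code{-0.1}).
#' @param lnc_db name of the single lncRNA-target database (starBase-style).
#' @param db_support named probability vector over the number of databases
#'   supporting a true miRNA-mRNA edge; names must be integers >= 2 so
#'   every planted edge survives the two-database consensus rule.
#' @param n_prognostic number of planted prognostic genes (taken from the
#'   planted triplet lncRNAs and mRNAs).
#' @param hazard_log_ratio log hazard ratio per standard deviation of
#'   expression for each planted prognostic gene.
#' @param censor_frac target fraction of censored samples (independent
#'   uniform censoring).
#' @param base_rate baseline exponential hazard rate.
#' @param seed integer seed; every simulation function derives its stream
#'   from it, so a config fully determines all outputs.
#' @return list of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_lnc = 60, n_mirna = 30, n_mrna = 80,
                              n_case = 20, n_control = 20,
                              baseline_mean = 100, dispersion = 0.1,
                              n_triplets = 5, effect_log2fc = 4,
                              decoy_edges = 30, decoy_lnc_edges = 10,
                              db_names = c("miRDB", "miRTarBase",
                                           "TargetScan"),
                              score_db = "TargetScan",
                              lnc_db = "starBase",
                              db_support = c("2" = 0.5, "3" = 0.5),
                              n_prognostic = 2, hazard_log_ratio = 1.5,
                              censor_frac = 0.3, base_rate = 0.1,
                              seed = 1L) {
  cfg <- list(n_lnc = n_lnc, n_mirna = n_mirna, n_mrna = n_mrna,
              n_case = n_case, n_control = n_control,
              baseline_mean = baseline_mean, dispersion = dispersion,
              n_triplets = n_triplets, effect_log2fc = effect_log2fc,
              decoy_edges = decoy_edges, decoy_lnc_edges = decoy_lnc_edges,
              db_names = db_names, score_db = score_db, lnc_db = lnc_db,
              db_support = db_support, n_prognostic = n_prognostic,
              hazard_log_ratio = hazard_log_ratio,
              censor_frac = censor_frac, base_rate = base_rate,
              seed = as.integer(seed))
  sizes <- c(n_lnc, n_mirna, n_mrna, n_case, n_control)
  if (any(sizes < 1)) stop("all population and sample sizes must be >= 1")
  if (baseline_mean <= 0 || dispersion < 0)
    stop("baseline_mean must be positive and dispersion non-negative")
  if (n_triplets < 0 || effect_log2fc < 0)
    stop("n_triplets and effect_log2fc must be non-negative")
  if (n_triplets > min(n_lnc, n_mirna, n_mrna))
    stop("n_triplets exceeds the smallest RNA-class size; ",
         "disjoint planting is infeasible")
  supp <- as.integer(names(db_support))
  if (anyNA(supp) || any(supp < 2) || any(supp > length(db_names)))
    stop("db_support names must be integers in [2, length(db_names)]")
  if (abs(sum(db_support) - 1) > 1e-8)
    stop("db_support probabilities must sum to 1")
  if (!score_db %in% db_names) stop("score_db must be one of db_names")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-group count matrix with planted competing triplets
#'
#' Counts are negative binomial with gene-specific log-normal baseline
#' means and a shared dispersion. The first \code{n_triplets} genes of each
#' RNA class form disjoint planted triplets; within a triplet the lncRNA
#' and mRNA share a randomly chosen direction and the miRNA takes the
#' opposite one, and each planted gene's case-group mean is shifted by
#' \code{effect_log2fc} on the log2 scale in its direction. All other genes
#' are null.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{matrix} (an
#'   \code{\link{expression_matrix}}) and \code{truth} (class
#'   \code{"ground_truth"}: \code{planted_triplets} data.frame,
#'   \code{planted_de} named direction vector with \code{"null"} for
#'   unplanted genes, \code{true_edges} data.frame, \code{prognostic}
#'   named vector of hazard log-ratios).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc))
  mir_ids <- sprintf("MIR%04d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrna))
  gene_ids <- c(lnc_ids, mir_ids, mrna_ids)
  rna_class <- stats::setNames(
    rep(c("lncRNA", "miRNA", "mRNA"),
        c(config$n_lnc, config$n_mirna, config$n_mrna)), gene_ids)

  k <- config$n_triplets
  planted_de <- stats::setNames(rep("null", length(gene_ids)), gene_ids)
  if (k > 0) {
    lnc_dir <- sample(c("up", "down"), k, replace = TRUE)
    planted <- data.frame(lncrna = lnc_ids[seq_len(k)],
                          mirna = mir_ids[seq_len(k)],
                          mrna = mrna_ids[seq_len(k)],
                          lnc_direction = lnc_dir,
                          mirna_direction = ifelse(lnc_dir == "up",
                                                   "down", "up"),
                          mrna_direction = lnc_dir,
                          group = ifelse(lnc_dir == "up", "lnc_up",
                                         "lnc_down"),
                          stringsAsFactors = FALSE)
    planted_de[planted$lncrna] <- planted$lnc_direction
    planted_de[planted$mirna] <- planted$mirna_direction
    planted_de[planted$mrna] <- planted$mrna_direction
    true_edges <- rbind(
      data.frame(mirna = planted$mirna, target = planted$mrna,
                 target_class = "mRNA", stringsAsFactors = FALSE),
      data.frame(mirna = planted$mirna, target = planted$lncrna,
                 target_class = "lncRNA", stringsAsFactors = FALSE))
  } else {
    planted <- data.frame(lncrna = character(), mirna = character(),
                          mrna = character(), lnc_direction = character(),
                          mirna_direction = character(),
                          mrna_direction = character(),
                          group = character(),
                          stringsAsFactors = FALSE)
    true_edges <- data.frame(mirna = character(), target = character(),
                             target_class = character(),
                             stringsAsFactors = FALSE)
  }

  base_mu <- stats::rlnorm(length(gene_ids), log(config$baseline_mean), 1)
  shift <- ifelse(planted_de == "up", config$effect_log2fc,
                  ifelse(planted_de == "down", -config$effect_log2fc, 0))
  mu_case <- base_mu * 2^shift
  n_s <- config$n_case + config$n_control
  sample_ids <- c(sprintf("case_%03d", seq_len(config$n_case)),
                  sprintf("ctrl_%03d", seq_len(config$n_control)))
  group <- stats::setNames(rep(c("case", "control"),
                               c(config$n_case, config$n_control)),
                           sample_ids)
  draw <- function(n, mu) {
    if (config$dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
  }
  counts <- matrix(0, nrow = length(gene_ids), ncol = n_s,
                   dimnames = list(gene_ids, sample_ids))
  for (g in seq_along(gene_ids)) {
    counts[g, ] <- c(draw(config$n_case, mu_case[g]),
                     draw(config$n_control, base_mu[g]))
  }

  prognostic <- numeric(0)
  if (config$n_prognostic > 0) {
    # take the lncRNA and mRNA of the same triplet consecutively: they
    # share a DE direction, so their standardized-expression hazard
    # contributions reinforce rather than cancel
    pool <- if (k > 0) c(rbind(planted$lncrna, planted$mrna)) else gene_ids
    picks <- pool[seq_len(min(config$n_prognostic, length(pool)))]
    prognostic <- stats::setNames(rep(config$hazard_log_ratio,
                                      length(picks)), picks)
  }

  truth <- structure(list(planted_triplets = planted,
                          planted_de = planted_de,
                          true_edges = true_edges,
                          prognostic = prognostic),
                     class = "ground_truth")
  list(matrix = expression_matrix(counts, rna_class, group), truth = truth)
}

#' Simulate multi-database miRNA-target interaction tables
#'
#' Every true miRNA-mRNA edge from the ground truth is emitted in
#' \code{k >= 2} databases (\code{k} drawn from \code{db_support}), so it
#' always survives the two-database consensus rule; when the score-bearing
#' database is among them the edge is scored strictly below \code{-0.1}.
#' Decoy miRNA-mRNA edges appear in exactly one database; among decoys
#' that land in the score-bearing database, half are scored at or above
#' \code{-0.1} (removed by the score filter) and half below (removed by
#' consensus). True miRNA-lncRNA edges and their decoys go to the single
#' starBase-style table.
#'
#' @param truth \code{ground_truth} from \code{\link{simulate_counts}}.
#' @param config the same \code{\link{simulation_config}}.
#' @return named list of interaction data.frames, one per mRNA-target
#'   database plus one for the lncRNA-target database.
#' @export
simulate_interactions <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc))
  mir_ids <- sprintf("MIR%04d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrna))

  rec <- function(mirna, target, target_class, db, score = NA_real_) {
    data.frame(mirna = mirna, target = target, target_class = target_class,
               source_db = db, score = score, stringsAsFactors = FALSE)
  }
  tabs <- stats::setNames(
    rep(list(empty_interactions()), length(config$db_names) + 1),
    c(config$db_names, config$lnc_db))

  true_mm <- truth$true_edges[truth$true_edges$target_class == "mRNA", ,
                              drop = FALSE]
  supp_k <- as.integer(names(config$db_support))
  for (i in seq_len(nrow(true_mm))) {
    k <- if (length(supp_k) == 1) supp_k else
      sample(supp_k, 1, prob = config$db_support)
    dbs <- sample(config$db_names, k)
    for (db in dbs) {
      sc <- if (db == config$score_db) stats::runif(1, -0.9, -0.101)
            else NA_real_
      tabs[[db]] <- rbind(tabs[[db]],
                          rec(true_mm$mirna[i], true_mm$target[i], "mRNA",
                              db, sc))
    }
  }

  # decoy mRNA edges: unique pairs not among the true edges
  if (config$decoy_edges > 0) {
    true_key <- paste(true_mm$mirna, true_mm$target)
    pool_size <- config$n_mirna * config$n_mrna - nrow(true_mm)
    if (config$decoy_edges > pool_size)
      stop("decoy_edges exceeds the number of available miRNA-mRNA pairs")
    decoys <- character(0)
    while (length(decoys) < config$decoy_edges) {
      cand <- paste(sample(mir_ids, config$decoy_edges, replace = TRUE),
                    sample(mrna_ids, config$decoy_edges, replace = TRUE))
      decoys <- utils::head(unique(c(decoys, setdiff(cand, true_key))),
                            config$decoy_edges)
    }
    decoy_db <- sample(config$db_names, length(decoys), replace = TRUE)
    score_decoy_flip <- TRUE
    for (i in seq_along(decoys)) {
      pair <- strsplit(decoys[i], " ", fixed = TRUE)[[1]]
      db <- decoy_db[i]
      sc <- NA_real_
      if (db == config$score_db) {
        # alternate: half at/above the -0.1 cut, half below
        sc <- if (score_decoy_flip) stats::runif(1, -0.1, 0.5)
              else stats::runif(1, -0.9, -0.101)
        score_decoy_flip <- !score_decoy_flip
      }
      tabs[[db]] <- rbind(tabs[[db]], rec(pair[1], pair[2], "mRNA", db, sc))
    }
  }

  true_ml <- truth$true_edges[truth$true_edges$target_class == "lncRNA", ,
                              drop = FALSE]
  if (nrow(true_ml) > 0)
    tabs[[config$lnc_db]] <- rbind(
      tabs[[config$lnc_db]],
      rec(true_ml$mirna, true_ml$target, "lncRNA", config$lnc_db))
  if (config$decoy_lnc_edges > 0) {
    true_key <- paste(true_ml$mirna, true_ml$target)
    decoys <- character(0)
    while (length(decoys) < config$decoy_lnc_edges) {
      cand <- paste(sample(mir_ids, config$decoy_lnc_edges, replace = TRUE),
                    sample(lnc_ids, config$decoy_lnc_edges, replace = TRUE))
      decoys <- utils::head(unique(c(decoys, setdiff(cand, true_key))),
                            config$decoy_lnc_edges)
    }
    for (d in decoys) {
      pair <- strsplit(d, " ", fixed = TRUE)[[1]]
      tabs[[config$lnc_db]] <- rbind(
        tabs[[config$lnc_db]],
        rec(pair[1], pair[2], "lncRNA", config$lnc_db))
    }
  }
  for (nm in names(tabs)) rownames(tabs[[nm]]) <- NULL
  tabs
}

#' Simulate a clinical survival table tied to planted prognostic genes
#'
#' Survival times are exponential with per-sample log hazard equal to the
#' sum over prognostic genes of (hazard log-ratio x standardized log2 CPM).
#' Censoring is independent uniform on (0, u) with u solved so that the
#' expected censored fraction at the baseline hazard matches
#' \code{censor_frac}.
#'
#' @param mat an \code{\link{expression_matrix}} containing the prognostic
#'   genes.
#' @param truth \code{ground_truth} with a non-empty \code{prognostic}
#'   vector.
#' @param config the \code{\link{simulation_config}}.
#' @return clinical data.frame (\code{sample_id}, \code{time},
#'   \code{event}) covering every sample of \code{mat}.
#' @export
simulate_survival <- function(mat, truth, config) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(truth, "ground_truth"))
  if (length(truth$prognostic) == 0)
    stop("ground truth has no prognostic genes")
  missing <- setdiff(names(truth$prognostic), rownames(mat$counts))
  if (length(missing) > 0)
    stop("prognostic gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  set.seed(config$seed + 2L)
  expr <- log2(cpm(mat$counts) + 1)
  z <- scale(t(expr[names(truth$prognostic), , drop = FALSE]))
  z[is.nan(z)] <- 0  # constant gene: no prognostic signal
  loghaz <- drop(z %*% truth$prognostic)
  rate <- config$base_rate * exp(loghaz)
  t_event <- stats::rexp(length(rate), rate)
  u <- censor_upper(config$censor_frac) / config$base_rate
  t_cens <- stats::runif(length(rate), 0, u)
  data.frame(sample_id = colnames(mat$counts),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

# solve (1 - exp(-u))/u = frac for the uniform censoring upper bound
# (unit baseline hazard); the caller rescales by the actual rate
censor_upper <- function(frac) {
  if (frac <= 0) return(Inf)
  stats::uniroot(function(u) (1 - exp(-u)) / u - frac,
                 c(1e-6, 1e6))$root
}

#' Simulate a gene-set collection with one enriched set
#'
#' Builds \code{n_sets} random sets over the given universe plus one
#' "signal" set containing the planted mRNAs, so over-representation of
#' network mRNAs is recoverable by construction.
#'
#' @param truth \code{ground_truth}; its planted mRNAs seed the signal set.
#' @param universe character vector of mRNA ids to draw set members from.
#' @param n_sets number of random sets.
#' @param set_size range (min, max) of random set sizes.
#' @param seed integer seed.
#' @return a \code{\link{gene_set_collection}}; the signal set is named
#'   \code{"SIG_PLANTED"}.
#' @export
simulate_gene_sets <- function(truth, universe, n_sets = 20,
                               set_size = c(5, 25), seed = 1L) {
  set.seed(seed + 3L)
  sets <- list()
  desc <- character()
  planted <- intersect(truth$planted_triplets$mrna, universe)
  if (length(planted) > 0) {
    pad <- sample(setdiff(universe, planted),
                  min(3, length(setdiff(universe, planted))))
    sets[["SIG_PLANTED"]] <- c(planted, pad)
    desc["SIG_PLANTED"] <- "planted ceRNA-target mRNAs"
  }
  for (i in seq_len(n_sets)) {
    id <- sprintf("RND%03d", i)
    sz <- sample(seq(set_size[1], set_size[2]), 1)
    sets[[id]] <- sample(universe, min(sz, length(universe)))
    desc[id] <- "random set"
  }
  gene_set_collection(sets, desc)
}

#' Simulate a qPCR Ct table for one target against a reference gene
#'
#' Case samples express the target at \code{fold_change} times the control
#' level, i.e. their target Ct is lower by \code{log2(fold_change)} cycles;
#' the reference gene is flat. Gaussian replicate noise on the Ct scale.
#'
#' @param n_case,n_control biological samples per condition.
#' @param n_replicates technical replicates per (sample, gene).
#' @param fold_change true case/control expression ratio of the target.
#' @param target_ct,ref_ct mean control-condition Ct of target and
#'   reference.
#' @param noise_sd replicate standard deviation (cycles).
#' @param seed integer seed.
#' @return Ct data.frame (\code{sample_id}, \code{condition}, \code{gene},
#'   \code{ct}, \code{replicate}) with gene in \code{{"target",
#'   "reference"}}.
#' @export
simulate_ct_table <- function(n_case = 3, n_control = 3, n_replicates = 3,
                              fold_change = 4, target_ct = 26, ref_ct = 16,
                              noise_sd = 0.15, seed = 1L) {
  set.seed(seed + 4L)
  rows <- list()
  add <- function(sample_id, condition, gene, mu) {
    data.frame(sample_id = sample_id, condition = condition, gene = gene,
               ct = stats::rnorm(n_replicates, mu, noise_sd),
               replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_case)) {
    id <- sprintf("case_%02d", i)
    rows[[length(rows) + 1]] <- add(id, "case", "target",
                                    target_ct - log2(fold_change))
    rows[[length(rows) + 1]] <- add(id, "case", "reference", ref_ct)
  }
  for (i in seq_len(n_control)) {
    id <- sprintf("ctrl_%02d", i)
    rows[[length(rows) + 1]] <- add(id, "control", "target", target_ct)
    rows[[length(rows) + 1]] <- add(id, "control", "reference", ref_ct)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
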