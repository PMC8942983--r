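#' Score-filter a TargetScan-style interaction table
#'
#' TargetScan-style exports rank predictions by a cumulative weighted
#' context score; more negative means stronger predicted repression. Only
#' records with \code{score} strictly below the threshold are kept.
#'
#' @param table interaction data.frame from the score-bearing database.
#' @param score_threshold cut-off; records with \code{score <
#'   score_threshold} survive (default \code{-0.1}).
#' @return the filtered interaction data.frame.
#' @export
filter_targetscan <- function(table, score_threshold = -0.1) {
  if (nrow(table) == 0) return(table)
  if (anyNA(table$score))
    stop("record(s) without a score in a score-bearing database: ",
         paste(utils::head(paste(table$mirna[is.na(table$score)],
                                 table$target[is.na(table$score)]), 5),
               collapse = "; "))
  out <- table[table$score < score_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus miRNA-mRNA target edges across databases
#'
#' A (miRNA, mRNA) pair counts as a target edge only when it appears in at
#' least \code{min_db} distinct databases. Support is counted over
#' distinct \code{source_db} values, never record multiplicity, so the
#' result is invariant to table order and to duplicated records. Apply
#' \code{\link{filter_targetscan}} to the score-bearing table first so a
#' sub-threshold record cannot count as support.
#'
#' @param tables a single interaction data.frame or a list of them (one
#'   per database).
#' @param min_db minimum number of distinct supporting databases
#'   (default 2).
#' @return data.frame with columns \code{mirna}, \code{mrna}, \code{n_db},
#'   \code{dbs} (comma-joined sorted database names), ordered by
#'   (\code{mirna}, \code{mrna}).
#' @export
consensus_mrna_targets <- function(tables, min_db = 2) {
  if (is.data.frame(tables)) tables <- list(tables)
  all_rec <- do.call(rbind, tables)
  all_rec <- all_rec[all_rec$target_class == "mRNA", , drop = FALSE]
  if (nrow(all_rec) == 0)
    return(data.frame(mirna = character(), mrna = character(),
                      n_db = integer(), dbs = character(),
                      stringsAsFactors = FALSE))
  key <- paste(all_rec$mirna, all_rec$target, sep = "\r")
  support <- tapply(all_rec$source_db, key,
                    function(d) sort(unique(d)), simplify = FALSE)
  keep <- names(support)[lengths(support) >= min_db]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    mrna = vapply(parts, `[`, "", 2),
                    n_db = lengths(support[keep]),
                    dbs = vapply(support[keep], paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA-lncRNA target edges from the single-source table
#'
#' The lncRNA side has no consensus rule (one starBase-style source);
#' this is a deduplicating pass-through.
#'
#' @param table interaction data.frame with \code{target_class ==
#'   "lncRNA"} records.
#' @return data.frame with columns \code{mirna}, \code{lncrna}, ordered.
#' @export
lncrna_targets <- function(table) {
  rec <- table[table$target_class == "lncRNA", , drop = FALSE]
  out <- unique(data.frame(mirna = rec$mirna, lncrna = rec$target,
                           stringsAsFactors = FALSE))
  out <- out[order(out$mirna, out$lncrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundle consensus edges for network assembly
#'
#' @param mirna_mrna output of \code{\link{consensus_mrna_targets}}.
#' @param mirna_lnc output of \code{\link{lncrna_targets}}.
#' @return list of class \code{"consensus_edges"}.
#' @export
consensus_edges <- function(mirna_mrna, mirna_lnc) {
  structure(list(mirna_mrna = mirna_mrna, mirna_lnc = mirna_lnc),
            class = "consensus_edges")
}

#' @export
print.consensus_edges <- function(x, ...) {
  cat(sprintf("consensus_edges: %d miRNA-mRNA, %d miRNA-lncRNA\n",
              nrow(x$mirna_mrna), nrow(x$mirna_lnc)))
  invisible(x)
}
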