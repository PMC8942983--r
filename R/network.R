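#' Direction-opposed lncRNA-miRNA and miRNA-mRNA pairs
#'
#' Keeps a consensus edge only when both endpoints passed DE screening and
#' their DE directions are opposite — the executable reading of "negatively
#' co-expressed" when the miRNA and mRNA/lncRNA profiles come from
#' different cohorts. When both endpoints of an edge were profiled in the
#' same cohort, an optional Pearson-correlation filter can be layered on
#' top (\code{cor_matrix}/\code{cor_threshold}).
#'
#' Edges touching a gene absent from the DE table are silently excluded;
#' the counts of exclusions are reported via \code{message}.
#'
#' @param de screened DE table covering lncRNAs, miRNAs and mRNAs.
#' @param edges a \code{\link{consensus_edges}} object.
#' @param cor_matrix optional genes x samples expression matrix (or
#'   \code{expr_matrix}) for the correlation filter; \code{NULL} (default)
#'   disables it.
#' @param cor_threshold keep a pair only if the sample-level Pearson
#'   correlation is below this value (default \code{-0.3}); ignored when
#'   \code{cor_matrix} is \code{NULL}.
#' @return list with data.frames \code{lnc_mi} (\code{lncrna},
#'   \code{mirna}, \code{lnc_direction}, \code{mirna_direction}) and
#'   \code{mi_mrna} (\code{mirna}, \code{mrna}, \code{mirna_direction},
#'   \code{mrna_direction}).
#' @export
build_pairs <- function(de, edges, cor_matrix = NULL, cor_threshold = -0.3) {
  stopifnot(inherits(edges, "consensus_edges"))
  dir <- stats::setNames(de$direction, de$gene_id)

  ml <- edges$mirna_lnc
  in_de_ml <- ml$mirna %in% names(dir) & ml$lncrna %in% names(dir)
  if (any(!in_de_ml))
    message(sum(!in_de_ml),
            " miRNA-lncRNA edge(s) dropped: endpoint not in DE table")
  ml <- ml[in_de_ml, , drop = FALSE]
  opp <- dir[ml$mirna] != dir[ml$lncrna]
  lnc_mi <- data.frame(lncrna = ml$lncrna[opp], mirna = ml$mirna[opp],
                       lnc_direction = unname(dir[ml$lncrna[opp]]),
                       mirna_direction = unname(dir[ml$mirna[opp]]),
                       stringsAsFactors = FALSE)

  mm <- edges$mirna_mrna
  in_de_mm <- mm$mirna %in% names(dir) & mm$mrna %in% names(dir)
  if (any(!in_de_mm))
    message(sum(!in_de_mm),
            " miRNA-mRNA edge(s) dropped: endpoint not in DE table")
  mm <- mm[in_de_mm, , drop = FALSE]
  opp <- dir[mm$mirna] != dir[mm$mrna]
  mi_mrna <- data.frame(mirna = mm$mirna[opp], mrna = mm$mrna[opp],
                        mirna_direction = unname(dir[mm$mirna[opp]]),
                        mrna_direction = unname(dir[mm$mrna[opp]]),
                        stringsAsFactors = FALSE)

  if (!is.null(cor_matrix)) {
    if (inherits(cor_matrix, "expr_matrix")) cor_matrix <- cor_matrix$counts
    keep_cor <- function(a, b) {
      ok <- a %in% rownames(cor_matrix) & b %in% rownames(cor_matrix)
      r <- rep(NA_real_, length(a))
      for (i in which(ok))
        r[i] <- stats::cor(cor_matrix[a[i], ], cor_matrix[b[i], ])
      ok & !is.na(r) & r < cor_threshold
    }
    lnc_mi <- lnc_mi[keep_cor(lnc_mi$lncrna, lnc_mi$mirna), , drop = FALSE]
    mi_mrna <- mi_mrna[keep_cor(mi_mrna$mirna, mi_mrna$mrna), , drop = FALSE]
  }
  rownames(lnc_mi) <- rownames(mi_mrna) <- NULL
  list(lnc_mi = lnc_mi, mi_mrna = mi_mrna)
}

#' Assemble co-expression competing triplets
#'
#' Joins the two pair sets on the shared miRNA: each (lncRNA, miRNA) pair
#' combined with each (miRNA, mRNA) pair of the same miRNA yields one
#' competing triplet. Because both partners oppose the same miRNA, the
#' lncRNA and mRNA necessarily share a direction; this is re-validated
#' here. The triplet group is \code{"lnc_up"} when the lncRNA is
#' upregulated, \code{"lnc_down"} otherwise.
#'
#' @param pairs output of \code{\link{build_pairs}} (or a list with
#'   compatible \code{lnc_mi} / \code{mi_mrna} data.frames).
#' @return data.frame ordered by (\code{lncrna}, \code{mirna},
#'   \code{mrna}) with columns \code{lncrna}, \code{mirna}, \code{mrna},
#'   direction columns for all three, and \code{group}.
#' @export
assemble_triplets <- function(pairs) {
  lnc_mi <- pairs$lnc_mi
  mi_mrna <- pairs$mi_mrna
  if (nrow(lnc_mi) == 0 || nrow(mi_mrna) == 0) return(empty_triplets())
  tri <- merge(lnc_mi, mi_mrna, by = "mirna",
               suffixes = c("", ".y"))
  if (nrow(tri) == 0) return(empty_triplets())
  if (!all(tri$mirna_direction == tri$mirna_direction.y))
    stop("inconsistent miRNA direction between pair sets")
  if (!all(tri$lnc_direction == tri$mrna_direction) ||
      any(tri$lnc_direction == tri$mirna_direction))
    stop("direction constraint violated: lncRNA and mRNA must share a ",
         "direction opposite to the miRNA")
  out <- data.frame(lncrna = tri$lncrna, mirna = tri$mirna,
                    mrna = tri$mrna,
                    lnc_direction = tri$lnc_direction,
                    mirna_direction = tri$mirna_direction,
                    mrna_direction = tri$mrna_direction,
                    group = ifelse(tri$lnc_direction == "up",
                                   "lnc_up", "lnc_down"),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_triplets <- function() {
  data.frame(lncrna = character(), mirna = character(), mrna = character(),
             lnc_direction = character(), mirna_direction = character(),
             mrna_direction = character(), group = character(),
             stringsAsFactors = FALSE)
}

#' Build the group ceRNA networks from competing triplets
#'
#' Triplets are partitioned by lncRNA direction into the lncRNA-upregulated
#' and lncRNA-downregulated groups; within each group, nodes and edges are
#' the union over triplets (edge multiplicity collapsed, each edge keeping
#' the number of triplets that induced it). Every constructed network is
#' validated to be tripartite with no isolated nodes.
#'
#' @param triplets data.frame from \code{\link{assemble_triplets}}.
#' @return list with elements \code{lnc_up} and \code{lnc_down}, each a
#'   \code{cerna_network}: list(\code{nodes}, \code{edges},
#'   \code{triplets}, \code{group}).
#' @export
build_network <- function(triplets) {
  nets <- lapply(c(lnc_up = "lnc_up", lnc_down = "lnc_down"), function(g) {
    cerna_network(triplets[triplets$group == g, , drop = FALSE], g)
  })
  for (g in names(nets))
    message(sprintf("%s: %d lncRNAs, %d miRNAs, %d mRNAs, %d edges", g,
                    sum(nets[[g]]$nodes$rna_class == "lncRNA"),
                    sum(nets[[g]]$nodes$rna_class == "miRNA"),
                    sum(nets[[g]]$nodes$rna_class == "mRNA"),
                    nrow(nets[[g]]$edges)))
  nets
}

#' @rdname build_network
#' @param group_label group name stored on the network.
#' @export
cerna_network <- function(triplets, group_label = "all") {
  if (nrow(triplets) == 0) {
    net <- structure(list(
      nodes = data.frame(id = character(), rna_class = character(),
                         direction = character(), stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         edge_type = character(), n_triplets = integer(),
                         stringsAsFactors = FALSE),
      triplets = triplets, group = group_label), class = "cerna_network")
    return(net)
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna, rna_class = "lncRNA",
               direction = triplets$lnc_direction, stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna, rna_class = "miRNA",
               direction = triplets$mirna_direction,
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna, rna_class = "mRNA",
               direction = triplets$mrna_direction,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(nodes$id))
    stop("gene id appears with conflicting class or direction: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  lm_key <- paste(triplets$lncrna, triplets$mirna, sep = "\r")
  mm_key <- paste(triplets$mirna, triplets$mrna, sep = "\r")
  edge_df <- function(keys, type) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, "", 1),
               to = vapply(parts, `[`, "", 2),
               edge_type = type, n_triplets = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_df(lm_key, "lncRNA-miRNA"),
                 edge_df(mm_key, "miRNA-mRNA"))
  edges <- edges[order(edges$edge_type, edges$from, edges$to), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges, triplets = triplets,
                        group = group_label), class = "cerna_network")
  validate_tripartite(net)
  net
}

#' Assert the tripartite structure of a ceRNA network
#'
#' lncRNA and mRNA nodes may only neighbor miRNA nodes, every edge must be
#' induced by at least one stored triplet, and no node may be isolated.
#'
#' @param net a \code{cerna_network}.
#' @return the network, invisibly; errors otherwise.
#' @export
validate_tripartite <- function(net) {
  cls <- stats::setNames(net$nodes$rna_class, net$nodes$id)
  e <- net$edges
  lm <- e[e$edge_type == "lncRNA-miRNA", , drop = FALSE]
  mm <- e[e$edge_type == "miRNA-mRNA", , drop = FALSE]
  if (nrow(lm) + nrow(mm) != nrow(e)) stop("unknown edge type present")
  if (!all(cls[lm$from] == "lncRNA") || !all(cls[lm$to] == "miRNA") ||
      !all(cls[mm$from] == "miRNA") || !all(cls[mm$to] == "mRNA"))
    stop("network is not tripartite")
  touched <- unique(c(e$from, e$to))
  if (!setequal(touched, net$nodes$id) && nrow(net$nodes) > 0)
    stop("isolated node(s): ",
         paste(setdiff(net$nodes$id, touched), collapse = ", "))
  if (any(e$n_triplets < 1)) stop("edge without a supporting triplet")
  invisible(net)
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network [%s]: %d nodes (%d lncRNA / %d miRNA / %d mRNA), %d edges, %d triplets\n",
              x$group, nrow(x$nodes),
              sum(x$nodes$rna_class == "lncRNA"),
              sum(x$nodes$rna_class == "miRNA"),
              sum(x$nodes$rna_class == "mRNA"),
              nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' Convert a ceRNA network to an igraph object
#'
#' Node attributes \code{rna_class} and \code{direction} and edge
#' attributes \code{edge_type} and \code{n_triplets} are carried over, so
#' GraphML exports keep them.
#'
#' @param net a \code{cerna_network}.
#' @return an undirected \code{igraph} graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}
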