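#' Node degrees of a ceRNA network
#'
#' Degree is the number of distinct incident edges (triplet multiplicity
#' is not counted).
#'
#' @param net a \code{cerna_network}.
#' @return named integer vector over all nodes, in node-table order.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  ends <- c(net$edges$from, net$edges$to)
  if (length(ends) > 0) {
    tab <- table(ends)
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Hub nodes: degree strictly exceeding a threshold
#'
#' "Exceeding" is read strictly, so the default flags nodes of degree 6
#' and above. Pass a list of group networks to pool them (union of nodes
#' and edges) before calling hubs.
#'
#' @param net a \code{cerna_network} or a list of them.
#' @param threshold degree cut (default 5); a node is a hub iff
#'   \code{degree > threshold}.
#' @return data.frame (\code{id}, \code{rna_class}, \code{degree}) sorted
#'   by decreasing degree then id, with the threshold as attribute
#'   \code{"threshold"}.
#' @export
hub_nodes <- function(net, threshold = 5) {
  if (!inherits(net, "cerna_network")) net <- pool_networks(net)
  deg <- node_degrees(net)
  keep <- deg > threshold
  out <- data.frame(id = names(deg)[keep],
                    rna_class = net$nodes$rna_class[keep],
                    degree = unname(deg[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Pool group networks into one network
#'
#' Union of triplets across groups, rebuilt as a single network (so a
#' shared edge's triplet count is summed and degrees reflect all groups).
#'
#' @param nets list of \code{cerna_network} objects.
#' @return a \code{cerna_network} with group label \code{"pooled"}.
#' @export
pool_networks <- function(nets) {
  stopifnot(is.list(nets), all(vapply(nets, inherits, TRUE,
                                      "cerna_network")))
  all_tri <- unique(do.call(rbind, lapply(nets, `[[`, "triplets")))
  cerna_network(all_tri, "pooled")
}

#' First/secondary relationship pairs of one lncRNA
#'
#' The first relationship pairs are the distinct lncRNA-miRNA edges
#' incident to the lncRNA (equal to its node degree in a tripartite
#' network); the secondary relationship pairs are the distinct miRNA-mRNA
#' edges whose miRNA is one of those neighbors — distinct edges, not
#' paths, so an mRNA reachable through two miRNAs contributes twice.
#' Total pairs is their sum.
#'
#' @param net a \code{cerna_network}.
#' @param lncrna_id id of an lncRNA node of the network.
#' @return one-row data.frame: \code{lncrna_id}, \code{node_degree},
#'   \code{first_pairs}, \code{secondary_pairs}, \code{total_pairs}.
#' @export
count_pairs <- function(net, lncrna_id) {
  stopifnot(inherits(net, "cerna_network"))
  cls <- stats::setNames(net$nodes$rna_class, net$nodes$id)
  if (!lncrna_id %in% names(cls))
    stop("unknown node id: ", lncrna_id)
  if (cls[[lncrna_id]] != "lncRNA")
    stop("'", lncrna_id, "' is not an lncRNA node")
  lm <- net$edges[net$edges$edge_type == "lncRNA-miRNA" &
                  net$edges$from == lncrna_id, , drop = FALSE]
  neighbors <- unique(lm$to)
  first <- length(neighbors)
  mm <- net$edges[net$edges$edge_type == "miRNA-mRNA" &
                  net$edges$from %in% neighbors, , drop = FALSE]
  secondary <- nrow(unique(mm[, c("from", "to")]))
  data.frame(lncrna_id = lncrna_id,
             node_degree = first,  # tripartite: lncRNAs only touch miRNAs
             first_pairs = first,
             secondary_pairs = secondary,
             total_pairs = first + secondary,
             stringsAsFactors = FALSE)
}

#' Topological ranking of all lncRNAs in a network
#'
#' Sorted by node degree (descending), then total pairs (descending),
#' then gene id (ascending) for determinism.
#'
#' @param net a \code{cerna_network}.
#' @return data.frame of \code{\link{count_pairs}} records with a
#'   \code{rank} column.
#' @export
rank_lncrnas <- function(net) {
  lncs <- net$nodes$id[net$nodes$rna_class == "lncRNA"]
  if (length(lncs) == 0)
    return(data.frame(rank = integer(), lncrna_id = character(),
                      node_degree = integer(), first_pairs = integer(),
                      secondary_pairs = integer(), total_pairs = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(lncs, count_pairs, net = net))
  out <- out[order(-out$node_degree, -out$total_pairs, out$lncrna_id), ,
             drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Select key lncRNAs by the top-k intersection rule
#'
#' A key lncRNA must be in the top \code{k} of the node-degree ranking AND
#' the top \code{k} of the total-pairs ranking (ties broken by the other
#' statistic, then lexicographically). Fewer than \code{k} ids may be
#' returned; a disjoint intersection returns an empty vector with a
#' warning.
#'
#' @param ranked output of \code{\link{rank_lncrnas}}.
#' @param k depth of each ranking (default 3).
#' @return character vector of key lncRNA ids, in degree-ranking order.
#' @export
select_key_lncrnas <- function(ranked, k = 3) {
  if (nrow(ranked) == 0) return(character(0))
  by_deg <- ranked[order(-ranked$node_degree, -ranked$total_pairs,
                         ranked$lncrna_id), "lncrna_id"]
  by_tot <- ranked[order(-ranked$total_pairs, -ranked$node_degree,
                         ranked$lncrna_id), "lncrna_id"]
  keys <- intersect(utils::head(by_deg, k), utils::head(by_tot, k))
  if (length(keys) == 0)
    warning("degree and total-pairs top-", k, " sets are disjoint; ",
            "no key lncRNA selected")
  keys
}

#' Extract the sub-network around one lncRNA
#'
#' The induced sub-network contains the lncRNA, its miRNA neighbors and
#' those miRNAs' mRNA neighbors (the "first mRNA neighbors"), with all
#' connecting edges — i.e. exactly the triplets through the lncRNA.
#' Idempotent: the sub-network of a sub-network is itself.
#'
#' @param net a \code{cerna_network}.
#' @param lncrna_id id of an lncRNA node.
#' @return a \code{cerna_network} (possibly a singleton if the lncRNA is
#'   isolated).
#' @export
extract_subnetwork <- function(net, lncrna_id) {
  cls <- stats::setNames(net$nodes$rna_class, net$nodes$id)
  if (!lncrna_id %in% names(cls)) stop("unknown node id: ", lncrna_id)
  if (cls[[lncrna_id]] != "lncRNA")
    stop("'", lncrna_id, "' is not an lncRNA node")
  tri <- net$triplets[net$triplets$lncrna == lncrna_id, , drop = FALSE]
  sub <- cerna_network(tri, net$group)
  if (nrow(tri) == 0) {
    # isolated lncRNA: keep it as a singleton
    sub$nodes <- net$nodes[net$nodes$id == lncrna_id, , drop = FALSE]
    rownames(sub$nodes) <- NULL
  }
  sub
}
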