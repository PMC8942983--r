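#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts how many of \code{n} draws (without
#' replacement) from a universe of size \code{N} fall in a category of
#' size \code{K}. This is the over-representation p-value behind
#' gene-set enrichment by gene counting. Computed through the
#' log-space-stable distribution function, so tiny tails do not underflow.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K category size in the universe.
#' @param n draw (query) size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != floor(vals)))
    stop("k, K, n, N must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set collection
#'
#' For each set with at least one query gene, tests whether the query
#' over-represents the set relative to the universe, using the
#' hypergeometric upper tail. Query genes outside the universe are dropped
#' (count reported via \code{message}); set members are intersected with
#' the universe before sizing. The \code{significant} flag uses the RAW
#' p-value against \code{alpha} — the convention of count-based web tools —
#' while the BH-adjusted p-value is always reported alongside, since raw-p
#' screening across many sets inflates findings.
#'
#' @param query character vector of gene ids (e.g. the mRNAs of a ceRNA
#'   network).
#' @param collection a \code{\link{gene_set_collection}}.
#' @param universe character vector of background gene ids (e.g. all
#'   screened mRNAs).
#' @param alpha significance cut on the raw p-value (default 0.05).
#' @return data.frame sorted by p-value with columns \code{set_id},
#'   \code{description}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{pvalue}, \code{adj_pvalue}, \code{significant}, \code{genes}
#'   (comma-joined overlap).
#' @export
enrich <- function(query, collection, universe, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    message(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    overlap <- intersect(query, members)
    if (length(overlap) == 0) return(NULL)
    data.frame(set_id = id,
               description = unname(collection$description[id]),
               k = length(overlap), K = length(members), n = n, N = N,
               pvalue = hypergeom_upper_tail(length(overlap),
                                             length(members), n, N),
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(),
                      adj_pvalue = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adj_pvalue <- stats::p.adjust(out$pvalue, "BH")
  out$significant <- out$pvalue < alpha
  out <- out[order(out$pvalue, out$set_id),
             c("set_id", "description", "k", "K", "n", "N", "pvalue",
               "adj_pvalue", "significant", "genes")]
  rownames(out) <- NULL
  out
}
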