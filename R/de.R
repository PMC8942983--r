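#' Counts-per-million normalization
#'
#' @param counts genes x samples count matrix.
#' @return matrix of the same shape with each column scaled to sum to 1e6.
#' @export
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero library size")
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Two-group differential-expression screen on count data
#'
#' A deliberately simple surrogate for a full count-model fit: counts are
#' library-size normalized to CPM, the fold change is
#' \code{log2((mean case CPM + 1) / (mean control CPM + 1))}, and the
#' p-value comes from a two-sided Welch test on \code{log2(CPM + 1)}.
#' Benjamini-Hochberg adjustment is applied within each RNA class, since
#' the three classes are screened as separate series. Externally computed
#' DE tables (e.g. from edgeR) can be imported instead via
#' \code{\link{read_de_table}} and merged with
#' \code{\link{merge_external_de}}.
#'
#' Genes that are constant within both groups get p = 1 when the group
#' means agree and p = 0 when they differ (the zero-variance limit of the
#' t statistic).
#'
#' @param mat an \code{\link{expression_matrix}} with at least two samples
#'   per group.
#' @return DE table: data.frame with columns \code{gene_id},
#'   \code{rna_class}, \code{log2fc}, \code{pvalue}, \code{adj_pvalue},
#'   \code{direction} (\code{"up"} iff \code{log2fc > 0}).
#' @export
test_differential <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  case <- names(mat$group)[mat$group == "case"]
  ctrl <- names(mat$group)[mat$group == "control"]
  if (length(case) < 2 || length(ctrl) < 2)
    stop("each group needs at least 2 samples (variance undefined)")
  x <- cpm(mat$counts)
  lx <- log2(x + 1)
  log2fc <- log2((rowMeans(x[, case, drop = FALSE]) + 1) /
                 (rowMeans(x[, ctrl, drop = FALSE]) + 1))
  pvalue <- vapply(rownames(x), function(g) {
    a <- lx[g, case]
    b <- lx[g, ctrl]
    tryCatch(stats::t.test(a, b)$p.value,
             error = function(e) {
               if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
             })
  }, numeric(1))
  out <- data.frame(gene_id = rownames(x),
                    rna_class = unname(mat$rna_class[rownames(x)]),
                    log2fc = unname(log2fc),
                    pvalue = unname(pvalue),
                    stringsAsFactors = FALSE)
  out$adj_pvalue <- stats::ave(out$pvalue, out$rna_class,
                               FUN = function(p) stats::p.adjust(p, "BH"))
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Retain differentially expressed genes at the screening thresholds
#'
#' Both inequalities are strict: a gene is retained iff
#' \code{|log2fc| > lfc_threshold} and \code{adj_pvalue < adjp_threshold}.
#' The operation is idempotent and tightening either threshold can only
#' shrink the result.
#'
#' @param de DE table from \code{\link{test_differential}} or
#'   \code{\link{read_de_table}}.
#' @param lfc_threshold absolute log2 fold-change cut (default 1).
#' @param adjp_threshold adjusted p-value cut (default 0.05).
#' @return the filtered DE table.
#' @export
screen_de <- function(de, lfc_threshold = 1, adjp_threshold = 0.05) {
  keep <- abs(de$log2fc) > lfc_threshold & de$adj_pvalue < adjp_threshold
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class up/down composition of a screened DE table
#'
#' @param de a (screened) DE table.
#' @param classes classes to report; defaults to the three RNA classes.
#' @return data.frame with one row per class: \code{rna_class},
#'   \code{n_total}, \code{n_up}, \code{n_down} and \code{pct_up}
#'   (\code{100 * n_up / n_total} rounded to 2 decimals; \code{NA} for an
#'   empty class).
#' @export
summarize_directions <- function(de,
                                 classes = c("lncRNA", "miRNA", "mRNA")) {
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- de[de$rna_class == cl, , drop = FALSE]
    n_up <- sum(sub$direction == "up")
    data.frame(rna_class = cl, n_total = nrow(sub), n_up = n_up,
               n_down = nrow(sub) - n_up,
               pct_up = if (nrow(sub) == 0) NA_real_ else
                 round(100 * n_up / nrow(sub), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Merge externally supplied DE tables into a computed one
#'
#' Mirrors adding literature-reported differentially expressed genes to the
#' screened lists. Genes already present with the same direction are kept
#' once (the computed record wins); a gene imported with the opposite
#' direction is a hard error.
#'
#' @param de the computed DE table.
#' @param external a DE-table data.frame, a path readable by
#'   \code{\link{read_de_table}}, or a list of either.
#' @return the merged DE table.
#' @export
merge_external_de <- function(de, external) {
  if (!is.list(external) || is.data.frame(external))
    external <- list(external)
  for (ext in external) {
    if (is.character(ext)) ext <- read_de_table(ext)
    if (nrow(ext) == 0) next
    shared <- intersect(de$gene_id, ext$gene_id)
    if (length(shared) > 0) {
      d_old <- stats::setNames(de$direction, de$gene_id)[shared]
      d_new <- stats::setNames(ext$direction, ext$gene_id)[shared]
      bad <- shared[d_old != d_new]
      if (length(bad) > 0)
        stop("conflicting DE direction for gene(s): ",
             paste(bad, collapse = ", "))
    }
    de <- rbind(de, ext[!ext$gene_id %in% de$gene_id, , drop = FALSE])
  }
  rownames(de) <- NULL
  de
}
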