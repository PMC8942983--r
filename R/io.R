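#' Construct a validated expression matrix
#'
#' Bundles a genes x samples count matrix with the per-gene RNA class
#' (\code{"lncRNA"}, \code{"miRNA"} or \code{"mRNA"}) and the per-sample
#' group label (\code{"case"} or \code{"control"}). All downstream screening
#' functions take this container.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); all entries must be
#'   non-negative.
#' @param rna_class character vector named by gene id with values in
#'   \code{c("lncRNA", "miRNA", "mRNA")}.
#' @param group character vector named by sample id with values in
#'   \code{c("case", "control")}.
#' @return An object of class \code{"expr_matrix"}: a list with elements
#'   \code{counts}, \code{rna_class} and \code{group}.
#' @export
expression_matrix <- function(counts, rna_class, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  storage.mode(counts) <- "double"
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  rna_class <- rna_class[rownames(counts)]
  if (anyNA(rna_class))
    stop("rna_class missing for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(rna_class)], 5),
               collapse = ", "))
  if (!all(rna_class %in% c("lncRNA", "miRNA", "mRNA")))
    stop("rna_class values must be one of lncRNA, miRNA, mRNA")
  group <- group[colnames(counts)]
  if (anyNA(group))
    stop("group missing for sample(s): ",
         paste(utils::head(colnames(counts)[is.na(group)], 5),
               collapse = ", "))
  if (!all(group %in% c("case", "control")))
    stop("group values must be 'case' or 'control'")
  names(rna_class) <- rownames(counts)
  names(group) <- colnames(counts)
  structure(list(counts = counts, rna_class = rna_class, group = group),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(x$rna_class)), table(x$rna_class)),
            collapse = ", "), "\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
            collapse = ", "), "\n")
  invisible(x)
}

read_id_map <- function(x, what) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    df <- utils::read.delim(x, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop(what, " map file must have two columns")
    stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  } else if (!is.null(names(x))) {
    x
  } else {
    stop(what, " map must be a named vector or a two-column TSV path")
  }
}

#' Read a counts TSV into an expression matrix
#'
#' The TSV must have a header row of sample ids and gene ids in the first
#' column. Gene classes and sample groups are supplied as named vectors or
#' as paths to two-column TSV files (id, label).
#'
#' @param path path to the counts TSV.
#' @param class_map named character vector (gene id -> RNA class) or path
#'   to a two-column TSV.
#' @param group_map named character vector (sample id -> group) or path to
#'   a two-column TSV.
#' @param on_unknown_class what to do with genes missing from
#'   \code{class_map}: \code{"error"} (default) or \code{"drop"} (dropped
#'   rows are reported via \code{message}).
#' @return an \code{\link{expression_matrix}}.
#' @export
read_counts <- function(path, class_map, group_map,
                        on_unknown_class = c("error", "drop")) {
  on_unknown_class <- match.arg(on_unknown_class)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric cells in counts TSV ", path)
  rownames(counts) <- gene_ids
  class_map <- read_id_map(class_map, "class")
  group_map <- read_id_map(group_map, "group")
  unknown <- setdiff(gene_ids, names(class_map))
  if (length(unknown) > 0) {
    if (on_unknown_class == "error")
      stop("gene(s) with unknown RNA class: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    message(length(unknown), " gene(s) with unknown RNA class dropped")
    counts <- counts[setdiff(gene_ids, unknown), , drop = FALSE]
  }
  expression_matrix(counts, class_map, group_map)
}

#' Write an expression matrix as TSV files
#'
#' Writes \code{<stem>.tsv} (counts), \code{<stem>_classes.tsv} and
#' \code{<stem>_groups.tsv} so the matrix round-trips through
#' \code{\link{read_counts}}.
#'
#' @param mat an \code{expr_matrix}.
#' @param stem output path stem (no extension).
#' @return invisibly, the three paths written.
#' @export
write_counts <- function(mat, stem) {
  counts_path <- paste0(stem, ".tsv")
  df <- data.frame(gene = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  class_path <- paste0(stem, "_classes.tsv")
  utils::write.table(
    data.frame(gene = names(mat$rna_class), class = mat$rna_class),
    class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  group_path <- paste0(stem, "_groups.tsv")
  utils::write.table(
    data.frame(sample = names(mat$group), group = mat$group),
    group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, class_path, group_path))
}

#' Read miRNA-target interaction tables
#'
#' Each TSV emulates one database export and must have columns
#' \code{miRNA}, \code{target} and optionally \code{score}. Duplicate
#' (miRNA, target) records within one database are collapsed (reported via
#' \code{message}); the same pair in different databases is kept as
#' separate records, which is what the consensus step counts.
#'
#' @param paths character vector of TSV paths.
#' @param db_names database name per path (same length as \code{paths}).
#' @param target_class \code{"mRNA"} or \code{"lncRNA"}; recycled across
#'   paths.
#' @return data.frame with columns \code{mirna}, \code{target},
#'   \code{target_class}, \code{source_db}, \code{score} (NA when the
#'   export carries no score).
#' @export
read_interactions <- function(paths, db_names, target_class = "mRNA") {
  if (length(paths) != length(db_names))
    stop("paths and db_names must have the same length")
  target_class <- rep_len(target_class, length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (file.size(paths[i]) == 0) {
      out[[i]] <- empty_interactions()
      next
    }
    df <- utils::read.delim(paths[i], header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("miRNA", "target") %in% names(df)))
      stop("interaction TSV ", paths[i], " needs columns miRNA, target")
    if (nrow(df) == 0) {
      out[[i]] <- empty_interactions()
      next
    }
    rec <- data.frame(mirna = as.character(df$miRNA),
                      target = as.character(df$target),
                      target_class = target_class[i],
                      source_db = db_names[i],
                      score = if ("score" %in% names(df))
                        as.numeric(df$score) else NA_real_,
                      stringsAsFactors = FALSE)
    dup <- duplicated(rec[, c("mirna", "target")])
    if (any(dup))
      message(sum(dup), " duplicate record(s) collapsed in ", db_names[i])
    out[[i]] <- rec[!dup, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_interactions <- function() {
  data.frame(mirna = character(), target = character(),
             target_class = character(), source_db = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Write one interaction table as a database-style TSV
#'
#' @param table interaction data.frame (one \code{source_db}).
#' @param path output TSV path.
#' @param with_score include the score column.
#' @export
write_interactions <- function(table, path, with_score = FALSE) {
  df <- data.frame(miRNA = table$mirna, target = table$target,
                   stringsAsFactors = FALSE)
  if (with_score) df$score <- table$score
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, \code{set_id TAB description TAB
#' member...}. Lines with fewer than three fields are an error (reported
#' with the line number).
#'
#' @param path GMT file path.
#' @return object of class \code{"gene_set_collection"}: list with
#'   \code{sets} (named list of character vectors) and \code{description}
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need at least 3",
                   i, length(fields)))
    id <- fields[1]
    if (id %in% names(sets)) stop("duplicate set id: ", id)
    members <- unique(fields[-(1:2)])
    if (length(members) == 0) stop("empty gene set at line ", i)
    sets[[id]] <- members
    desc[id] <- fields[2]
  }
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (member gene ids).
#' @param description named character vector of set descriptions; defaults
#'   to the set ids.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  if (is.null(description)) description <- stats::setNames(names(sets),
                                                           names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a \code{gene_set_collection} to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$description[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write differential-expression tables
#'
#' The TSV schema (columns \code{gene}, \code{class}, \code{log2FC},
#' \code{pvalue}, \code{adj_pvalue}, \code{direction}) is also the import
#' path for externally computed DE results (e.g. an edgeR top table
#' reshaped to these columns).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{gene_id}, \code{rna_class},
#'   \code{log2fc}, \code{pvalue}, \code{adj_pvalue}, \code{direction}.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "class", "log2FC", "pvalue", "adj_pvalue", "direction")
  if (!all(need %in% names(df)))
    stop("DE table ", path, " needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(gene_id = as.character(df$gene),
                    rna_class = as.character(df$class),
                    log2fc = as.numeric(df$log2FC),
                    pvalue = as.numeric(df$pvalue),
                    adj_pvalue = as.numeric(df$adj_pvalue),
                    direction = as.character(df$direction),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene id in DE table: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  out
}

#' @rdname read_de_table
#' @param de DE table as returned by \code{\link{test_differential}}.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(
    data.frame(gene = de$gene_id, class = de$rna_class, log2FC = de$log2fc,
               pvalue = de$pvalue, adj_pvalue = de$adj_pvalue,
               direction = de$direction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write clinical survival tables
#'
#' @param path TSV with columns \code{sample}, \code{time}, \code{event}
#'   (1 = death observed, 0 = censored).
#' @return data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(df)))
    stop("clinical TSV needs columns sample, time, event")
  out <- data.frame(sample_id = as.character(df$sample),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  validate_clinical(out)
  out
}

validate_clinical <- function(clin) {
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample id in clinical table")
  if (any(clin$time <= 0)) stop("survival times must be positive")
  if (!all(clin$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  invisible(clin)
}

#' @rdname read_clinical
#' @param clin clinical data.frame (\code{sample_id}, \code{time},
#'   \code{event}).
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(
    data.frame(sample = clin$sample_id, time = clin$time, event = clin$event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ceRNA network for Cytoscape
#'
#' \code{"sif"} writes the simple-interaction format (source, interaction
#' type, target); \code{"graphml"} writes GraphML with \code{rna_class}
#' and \code{direction} node attributes; \code{"tsv"} writes the full edge
#' table.
#'
#' @param network a \code{cerna_network}.
#' @param path output file path.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "cerna_network"))
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", network$edges$from,
                     network$edges$edge_type, network$edges$to)
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read/write competing-triplet tables
#'
#' @param path TSV with columns \code{lncRNA}, \code{miRNA}, \code{mRNA},
#'   \code{group}.
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("lncRNA", "miRNA", "mRNA", "group")
  if (!all(need %in% names(df)))
    stop("triplet TSV needs columns: ", paste(need, collapse = ", "))
  data.frame(lncrna = df$lncRNA, mirna = df$miRNA, mrna = df$mRNA,
             group = df$group, stringsAsFactors = FALSE)
}

#' @rdname read_triplets
#' @param triplets triplet data.frame from \code{\link{assemble_triplets}}.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.table(
    data.frame(lncRNA = triplets$lncrna, miRNA = triplets$mirna,
               mRNA = triplets$mrna, group = triplets$group),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
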