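#' Median split of per-sample expression values
#'
#' Samples strictly above the median are \code{"high"}; samples at or
#' below it are \code{"low"} (ties go to low, deterministically). All-equal
#' values cannot be split and raise an error.
#'
#' @param values named numeric vector of per-sample expression for one
#'   gene.
#' @return character vector of \code{"high"}/\code{"low"} labels with the
#'   same names.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least two samples to split")
  m <- stats::median(values)
  labels <- ifelse(values > m, "high", "low")
  if (length(unique(labels)) < 2)
    stop("degenerate split: all values on one side of the median")
  stats::setNames(labels, names(values))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i); a
#' right-continuous, non-increasing step function starting at 1.
#'
#' @param times observed times (event or censoring).
#' @param events 1 = event observed, 0 = censored.
#' @return list of class \code{"km_curve"} with \code{time} (ascending
#'   distinct observed times), \code{n_risk}, \code{n_event}, \code{surv}.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events) || length(times) == 0)
    stop("times and events must be non-empty and the same length")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = round(x$surv, 4)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' The standard (O - E)^2 form with hypergeometric variance at each event
#' time; the p-value comes from a chi-square with one degree of freedom.
#'
#' @param times observed times.
#' @param events 1 = event, 0 = censored.
#' @param groups two-level group labels, one per subject.
#' @return list of class \code{"logrank_result"} with \code{chi_square},
#'   \code{pvalue} and \code{group_sizes}.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2)
    stop("exactly two groups are required (got ", length(lev), ")")
  sizes <- table(groups)
  if (any(sizes == 0)) stop("a group has zero subjects")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi <- unname(fit$chisq)
  structure(list(chi_square = chi,
                 pvalue = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 group_sizes = stats::setNames(as.integer(sizes),
                                               names(sizes))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4f (df = 1), p = %.4g; n = %s\n",
              x$chi_square, x$pvalue,
              paste(sprintf("%s:%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Prognostic screening of genes by median-split log-rank tests
#'
#' For each gene: samples are dichotomized at the median of log2(CPM + 1)
#' expression and the two arms compared by the log-rank test. A gene is
#' flagged iff p < alpha (strict). No multiple-testing correction is
#' applied across genes — the p-values are reported uncorrected, matching
#' the per-gene screening convention of survival web tools; interpret
#' accordingly.
#'
#' Genes whose expression cannot be split (all values equal) get
#' \code{NA} p-values and are never flagged.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param clinical clinical data.frame (\code{sample_id}, \code{time},
#'   \code{event}); only samples present in both inputs are used.
#' @param gene_ids genes to screen.
#' @param alpha significance cut (default 0.05).
#' @return data.frame: \code{gene_id}, \code{chi_square}, \code{pvalue},
#'   \code{n_high}, \code{n_low}, \code{flagged}.
#' @export
screen_prognostic <- function(mat, clinical, gene_ids, alpha = 0.05) {
  stopifnot(inherits(mat, "expr_matrix"))
  validate_clinical(clinical)
  if (length(gene_ids) == 0)
    return(data.frame(gene_id = character(), chi_square = numeric(),
                      pvalue = numeric(), n_high = integer(),
                      n_low = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))
  samples <- intersect(colnames(mat$counts), clinical$sample_id)
  if (length(samples) < 4)
    stop("need at least 4 samples shared between matrix and clinical table")
  clin <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  expr <- log2(cpm(mat$counts)[, samples, drop = FALSE] + 1)
  missing <- setdiff(gene_ids, rownames(expr))
  if (length(missing) > 0)
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  rows <- lapply(gene_ids, function(g) {
    grp <- tryCatch(median_split(expr[g, ]), error = function(e) NULL)
    if (is.null(grp))
      return(data.frame(gene_id = g, chi_square = NA_real_,
                        pvalue = NA_real_, n_high = NA_integer_,
                        n_low = NA_integer_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    lr <- logrank_test(clin$time, clin$event, grp)
    data.frame(gene_id = g, chi_square = lr$chi_square,
               pvalue = lr$pvalue,
               n_high = unname(lr$group_sizes["high"]),
               n_low = unname(lr$group_sizes["low"]),
               flagged = lr$pvalue < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
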