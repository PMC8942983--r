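#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale first. Per sample,
#' dCt = mean Ct(target) - mean Ct(reference); ddCt is each sample's dCt
#' minus the mean dCt of the control condition; the fold change is
#' 2^(-ddCt). Control samples are normalized against their own mean, so
#' their folds average to 1 on the log scale.
#'
#' @param ct_table data.frame with columns \code{sample_id},
#'   \code{condition} (\code{"case"}/\code{"control"}), \code{gene}
#'   (\code{"target"}/\code{"reference"}), \code{ct}, \code{replicate}.
#' @return data.frame per sample: \code{sample_id}, \code{condition},
#'   \code{delta_ct}, \code{delta_delta_ct}, \code{fold}.
#' @export
delta_delta_ct <- function(ct_table) {
  need <- c("sample_id", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (!all(ct_table$gene %in% c("target", "reference")))
    stop("gene must be 'target' or 'reference'")
  samples <- unique(ct_table$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- ct_table[ct_table$sample_id == s, , drop = FALSE]
    tgt <- sub$ct[sub$gene == "target"]
    ref <- sub$ct[sub$gene == "reference"]
    if (length(ref) == 0)
      stop("missing reference gene for sample ", s)
    if (length(tgt) == 0)
      stop("missing target gene for sample ", s)
    data.frame(sample_id = s, condition = sub$condition[1],
               delta_ct = mean(tgt) - mean(ref), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ctrl_mean <- mean(out$delta_ct[out$condition == "control"])
  if (is.nan(ctrl_mean)) stop("no control samples in Ct table")
  out$delta_delta_ct <- out$delta_ct - ctrl_mean
  out$fold <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' Two-group comparison of fold changes
#'
#' Classical equal-variance Student's t test by default (\code{var_equal =
#' FALSE} gives Welch). Means and standard deviations per group are
#' reported alongside.
#'
#' @param folds_case,folds_control numeric vectors of per-sample fold
#'   changes (each of length >= 2).
#' @param var_equal assume equal variances (default TRUE).
#' @return list: \code{t}, \code{df}, \code{pvalue}, \code{mean_case},
#'   \code{sd_case}, \code{mean_control}, \code{sd_control}.
#' @export
compare_groups <- function(folds_case, folds_control, var_equal = TRUE) {
  if (length(folds_case) < 2 || length(folds_control) < 2)
    stop("need at least 2 values per group (variance undefined)")
  tt <- stats::t.test(folds_case, folds_control, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value,
       mean_case = mean(folds_case), sd_case = stats::sd(folds_case),
       mean_control = mean(folds_control),
       sd_control = stats::sd(folds_control))
}
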