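make_de_matrix <- function(counts, classes = NULL) {
  n <- nrow(counts)
  if (is.null(classes)) classes <- rep("mRNA", n)
  rownames(counts) <- sprintf("g%02d", seq_len(n))
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  half <- ncol(counts) / 2
  expression_matrix(
    counts,
    stats::setNames(classes, rownames(counts)),
    stats::setNames(rep(c("case", "control"), each = half),
                    colnames(counts)))
}

test_that("fold change and p-value behave on constructed matrices", {
  # identical values in both groups: log2fc 0, p 1
  flat <- make_de_matrix(matrix(50, nrow = 3, ncol = 4))
  de <- test_differential(flat)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3))

  # case CPM doubled at equal library sizes: log2fc ~ 1 for all real genes
  ctrl <- c(1000, 2000, 500, 1500)
  case <- 2 * ctrl
  counts <- cbind(c(case, 0), c(case, 0),
                  c(ctrl, sum(ctrl)), c(ctrl, sum(ctrl)))
  doubled <- make_de_matrix(counts)
  de2 <- test_differential(doubled)
  expect_equal(de2$log2fc[1:4], rep(1, 4), tolerance = 1e-3)
  expect_true(all(de2$direction[1:4] == "up"))

  # fewer than 2 samples per group is an error
  expect_error(test_differential(make_de_matrix(matrix(1:6, 3, 2))),
               "at least 2 samples")
})

test_that("BH adjustment is applied within RNA class by the step-up rule", {
  # hand application of BH to p = (.01,.02,.03,.04): all adjust to .04
  # frozen step-up oracle: adj_i = min over j >= i of p_(j) * m / j
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # and test_differential adjusts within class, never pooled
  set.seed(42)
  counts <- matrix(rpois(8 * 8, 100), nrow = 8)
  mat <- make_de_matrix(counts, classes = rep(c("mRNA", "miRNA"), each = 4))
  de <- test_differential(mat)
  for (cl in c("mRNA", "miRNA")) {
    p <- de$pvalue[de$rna_class == cl]
    expect_equal(de$adj_pvalue[de$rna_class == cl],
                 stats::p.adjust(p, "BH"))
  }
  pooled <- stats::p.adjust(de$pvalue, "BH")
  expect_false(isTRUE(all.equal(pooled, de$adj_pvalue)))
})

test_that("screening uses strict thresholds, is idempotent and monotone", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    rna_class = "mRNA",
    log2fc = c(2.0, 1.0, -3.0, -1.5),
    pvalue = c(0.001, 0.0001, 0.01, 0.002),
    adj_pvalue = c(0.01, 0.001, 0.05, 0.002),
    direction = c("up", "up", "down", "down"),
    stringsAsFactors = FALSE)
  kept <- screen_de(de)
  # |lfc| = 1 exactly and adj_p = 0.05 exactly are both excluded
  expect_setequal(kept$gene_id, c("a", "d"))
  expect_identical(screen_de(kept), kept)
  tighter <- screen_de(de, lfc_threshold = 1.8)
  expect_true(all(tighter$gene_id %in% kept$gene_id))
  tighter2 <- screen_de(de, adjp_threshold = 0.005)
  expect_true(all(tighter2$gene_id %in% kept$gene_id))
})

test_that("direction summary reproduces printed-count percentages", {
  make_class <- function(cl, n, n_up) {
    data.frame(gene_id = sprintf("%s%04d", cl, seq_len(n)), rna_class = cl,
               log2fc = c(rep(2, n_up), rep(-2, n - n_up)),
               pvalue = 0.001, adj_pvalue = 0.01,
               direction = c(rep("up", n_up), rep("down", n - n_up)),
               stringsAsFactors = FALSE)
  }
  de <- rbind(make_class("mRNA", 127, 76),
              make_class("lncRNA", 3380, 1751),
              make_class("miRNA", 82, 19))
  s <- summarize_directions(de)
  expect_equal(s$pct_up[s$rna_class == "mRNA"], 59.84)
  expect_equal(s$pct_up[s$rna_class == "lncRNA"], 51.80)
  expect_equal(s$pct_up[s$rna_class == "miRNA"], 23.17)
  expect_true(all(s$n_up + s$n_down == s$n_total))

  zero_up <- summarize_directions(make_class("mRNA", 10, 0))
  expect_equal(zero_up$pct_up[zero_up$rna_class == "mRNA"], 0)
  expect_true(is.na(zero_up$pct_up[zero_up$rna_class == "lncRNA"]))
  expect_equal(zero_up$n_total[zero_up$rna_class == "lncRNA"], 0)
})

test_that("external DE tables merge by union and reject direction conflicts", {
  de <- data.frame(gene_id = c("XIST", "TUG1"), rna_class = "lncRNA",
                   log2fc = c(2, 3), pvalue = 0.001, adj_pvalue = 0.01,
                   direction = "up", stringsAsFactors = FALSE)
  lit <- data.frame(gene_id = c("H19", "NEAT1"), rna_class = "lncRNA",
                    log2fc = c(1.5, -2), pvalue = 0.01, adj_pvalue = 0.02,
                    direction = c("up", "down"), stringsAsFactors = FALSE)
  merged <- merge_external_de(de, lit)
  expect_equal(nrow(merged), 4)

  conflict <- data.frame(gene_id = "XIST", rna_class = "lncRNA",
                         log2fc = -2, pvalue = 0.01, adj_pvalue = 0.02,
                         direction = "down", stringsAsFactors = FALSE)
  expect_error(merge_external_de(de, conflict), "XIST")

  empty <- lit[0, ]
  expect_identical(merge_external_de(de, empty), de)
})
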