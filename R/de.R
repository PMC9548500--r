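# Exact two-sided Wilcoxon rank-sum p by full enumeration of the
# C(n1 + n2, n1) assignments of the observed (possibly tied) ranks.
# Two-sided rule: 2 * min(P(W <= w), P(W >= w)), capped at 1.
wilcox_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  sums <- utils::combn(rk, n1, sum)
  p_lo <- mean(sums <= w_obs + 1e-9)
  p_hi <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation with tie correction and continuity correction,
# two-sided (the standard large-sample rank-sum recipe).
wilcox_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  ties <- table(rk)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Bonferroni adjustment
#'
#' Family-wise error control: each p-value is multiplied by the number of
#' tests `m` and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests (defaults to `length(p)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) abort("m must be >= length(p)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' For each gene, compares normalized expression between two disjoint cell
#' groups with a two-sided Wilcoxon rank-sum test (exact enumeration when
#' both groups have at most `exact_max_n` cells, tie- and
#' continuity-corrected normal approximation otherwise), and Bonferroni
#' adjustment over the genes actually tested. Fold changes are computed on
#' the linear normalized scale: `mean_X` is the group mean of
#' `exp(normalized) - 1` and
#' `log2FC = log2((mean_A + pseudocount) / (mean_B + pseudocount))`.
#' Genes are tested only when expressed in at least `min_pct` of either
#' group and `|log2FC| >= min_abs_log2fc_prefilter`.
#'
#' @param norm Normalized genes x cells matrix from [lognormalize()].
#' @param cells_a,cells_b Disjoint, nonempty barcode vectors.
#' @param min_pct Minimum expressed fraction in either group (default 0.1).
#' @param min_abs_log2fc_prefilter Minimum `|log2FC|` to test (default
#'   0.25).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @param exact_max_n Largest group size for exact enumeration (default 10).
#' @return A tibble, one row per *tested* gene, ordered by `p_value`:
#'   `gene_id`, `log2fc`, `p_value`, `p_adj` (Bonferroni, m = genes
#'   tested), `pct_a`, `pct_b`, `mean_a`, `mean_b`. The number of genes
#'   tested is attached as attribute `"n_tested"`.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.1,
                        min_abs_log2fc_prefilter = 0.25, pseudocount = 1.0,
                        exact_max_n = 10L) {
  if (length(intersect(cells_a, cells_b)) > 0) abort("groups must be disjoint")
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    abort("both groups must be nonempty")
  }
  missing <- setdiff(c(cells_a, cells_b), colnames(norm))
  if (length(missing) > 0) {
    abort(paste0("cells not in matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  lin_a <- linearize(a); lin_b <- linearize(b)
  mean_a <- Matrix::rowMeans(lin_a); mean_b <- Matrix::rowMeans(lin_b)
  pct_a <- Matrix::rowMeans(a > 0); pct_b <- Matrix::rowMeans(b > 0)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  test_gene <- pmax(pct_a, pct_b) >= min_pct &
    abs(log2fc) >= min_abs_log2fc_prefilter
  if (!any(test_gene)) {
    warn("all genes removed by prefilters; empty result")
    out <- tibble(gene_id = character(), log2fc = numeric(),
                  p_value = numeric(), p_adj = numeric(),
                  pct_a = numeric(), pct_b = numeric(),
                  mean_a = numeric(), mean_b = numeric())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  am <- as.matrix(a[test_gene, , drop = FALSE])
  bm <- as.matrix(b[test_gene, , drop = FALSE])
  exact <- ncol(am) <= exact_max_n && ncol(bm) <= exact_max_n
  pv <- vapply(seq_len(nrow(am)), function(i) {
    if (exact) wilcox_exact_p(am[i, ], bm[i, ])
    else wilcox_normal_p(am[i, ], bm[i, ])
  }, numeric(1))
  m_tested <- sum(test_gene)
  out <- tibble(
    gene_id = rownames(norm)[test_gene],
    log2fc = unname(log2fc[test_gene]),
    p_value = pv,
    p_adj = bonferroni_adjust(pv, m_tested),
    pct_a = unname(pct_a[test_gene]), pct_b = unname(pct_b[test_gene]),
    mean_a = unname(mean_a[test_gene]), mean_b = unname(mean_b[test_gene])
  )
  out <- out[order(out$p_value, out$gene_id), ]
  attr(out, "n_tested") <- m_tested
  out
}

#' Select differentially expressed genes from a DE table
#'
#' Thresholds a [wilcoxon_de()] table on absolute *linear* fold change and
#' adjusted p-value, the selection feeding over-representation analysis.
#'
#' @param de_table A [wilcoxon_de()] result.
#' @param fc_threshold Absolute linear fold-change threshold, strict
#'   (default 1.8, i.e. `|log2fc| > log2(1.8)`).
#' @param padj_threshold Adjusted-p threshold, strict (default 0.05).
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de_table, fc_threshold = 1.8, padj_threshold = 0.05) {
  de_table$gene_id[abs(de_table$log2fc) > log2(fc_threshold) &
                     de_table$p_adj < padj_threshold]
}
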