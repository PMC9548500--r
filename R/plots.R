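#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Null histogram with observed correlations marked
#'
#' Renders the unrelated-pair correlation null as a histogram and marks
#' each tested pair's observed Pearson r with a vertical line annotated by
#' its one-sided p-value.
#'
#' @param object A `clonality_result` from [test_clonality()].
#' @param bins Histogram bins (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clonality_result
#' @export
autoplot.clonality_result <- function(object, bins = 15, ...) {
  null_df <- tibble(r = unname(object$null_sample))
  obs <- object$pvalues
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$r),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_text(
      data = obs,
      ggplot2::aes(x = .data$r, y = Inf,
                   label = sprintf("%s\nr=%.2f, p=%.2g",
                                   .data$pair, .data$r, .data$p_value)),
      vjust = 1.1, hjust = 1.02, size = 3, colour = "red") +
    ggplot2::labs(x = "Pearson r (unrelated tumor pairs)", y = "pairs",
                  title = "CNA-profile similarity vs unrelated-pair null") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' `-log10(p_adj)` against `log2` fold change, with the significance line
#' at `-log10(padj_threshold)` and vertical fold-change guides at
#' `+/- log2(fc_threshold)`.
#'
#' @param de_table A [wilcoxon_de()] result.
#' @param fc_threshold Linear fold-change guide (default 1.5).
#' @param padj_threshold Adjusted-p guide (default 0.05).
#' @param label_genes Optional genes to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de_table, fc_threshold = 1.5, padj_threshold = 0.05,
                         label_genes = NULL) {
  df <- dplyr::mutate(
    de_table,
    neglog10 = -log10(pmax(.data$p_adj, 1e-300)),
    significant = .data$p_adj < padj_threshold &
      abs(.data$log2fc) > log2(fc_threshold))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglog10,
                                        colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(padj_threshold), colour = "red") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(label_genes)) {
    p <- p + ggplot2::geom_text(
      data = df[df$gene_id %in% label_genes, ],
      ggplot2::aes(label = .data$gene_id),
      vjust = -0.6, size = 3, colour = "black")
  }
  p
}

#' Genome-wide CNA heatmap
#'
#' Cells (rows) by genes in genomic order (columns), faceted per
#' chromosome, with a diverging palette: red amplification, blue deletion.
#'
#' @param cna A [infer_cna_matrix()] result or a [mean_cna_profiles()]
#'   result (then rows are group profiles).
#' @param max_cells Downsample rows beyond this count for display
#'   (default 500).
#' @return A ggplot object.
#' @export
plot_cna_heatmap <- function(cna, max_cells = 500) {
  if (inherits(cna, "cna_profiles")) {
    mat <- t(cna$profiles); genes <- cna$genes
  } else {
    mat <- t(cna$cna); genes <- cna$genes
  }
  if (nrow(mat) > max_cells) {
    mat <- mat[seq(1, nrow(mat), length.out = max_cells), , drop = FALSE]
  }
  df <- tibble(
    cell = rep(rownames(mat), times = ncol(mat)),
    gene_index = rep(seq_len(ncol(mat)), each = nrow(mat)),
    chromosome = rep(genes$chromosome, each = nrow(mat)),
    cna = as.vector(mat)
  )
  df$chromosome <- factor(df$chromosome,
                          levels = chromosome_order(genes$chromosome))
  df$cell <- factor(df$cell, levels = rownames(mat))
  lim <- max(abs(df$cna), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_index, y = .data$cell,
                                   fill = .data$cna)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::labs(x = "genes in genomic order", y = NULL, fill = "CNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Edited-cell fractions by sample and class
#'
#' @param summary A [summarize_editing()] result.
#' @return A ggplot bar chart of `edited_fraction` per stratum.
#' @export
plot_editing_fractions <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$sample_id, y = .data$edited_fraction,
                               fill = .data$cell_class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "edited fraction (covered cells)") +
    ggplot2::theme_minimal()
}
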