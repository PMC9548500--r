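#' Log-normalize a count matrix
#'
#' Scales each cell to `scale_factor` total counts and log-transforms:
#' `log(count / total * scale_factor + 1)`. Zeros map to exactly zero, so
#' the sparsity pattern is preserved.
#'
#' @param counts Genes x cells matrix (sparse or dense, non-negative).
#' @param scale_factor Per-cell scale, default 10,000.
#' @param log_base `"natural"` (default) or `"two"`.
#' @return A sparse genes x cells matrix of normalized values, with
#'   attributes `scale_factor` and `log_base`.
#' @export
lognormalize <- function(counts, scale_factor = 10000,
                         log_base = c("natural", "two")) {
  log_base <- match.arg(log_base)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    abort(paste0("cells with zero total count: ",
                 paste(utils::head(bad, 10), collapse = ", "),
                 if (sum(totals == 0) > 10) " ..." else ""))
  }
  norm <- counts
  per_entry_total <- rep.int(totals, diff(norm@p))
  norm@x <- log1p(norm@x / per_entry_total * scale_factor)
  if (log_base == "two") norm@x <- norm@x / log(2)
  attr(norm, "scale_factor") <- scale_factor
  attr(norm, "log_base") <- log_base
  norm
}

# linear normalized values (inverse of the log1p transform), sparse
linearize <- function(norm) {
  base <- attr(norm, "log_base") %||% "natural"
  lin <- norm
  lin@x <- if (identical(base, "two")) 2^lin@x - 1 else expm1(lin@x)
  lin
}

#' Per-cell quality-control metrics
#'
#' Computes, per cell: the number of detected genes, total UMI count,
#' mitochondrial count fraction, and the mean normalized expression over
#' housekeeping genes (on the log scale, matching the normalization that
#' precedes the housekeeping criterion).
#'
#' @param counts Genes x cells raw count matrix.
#' @param annotation Gene annotation with a `category` column flagging
#'   `mitochondrial` and `housekeeping` genes.
#' @param norm Optional pre-computed [lognormalize()] matrix; computed here
#'   when missing.
#' @param doublet_score Optional per-cell doublet score (named vector or
#'   tibble from [doublet_scores()]) to carry into the table.
#' @return A tibble with one row per cell: `cell_barcode`, `n_genes`,
#'   `n_umi`, `mito_ratio`, `hk_mean`, `doublet_score`.
#' @export
cell_qc_metrics <- function(counts, annotation, norm = NULL,
                            doublet_score = NULL) {
  check_annotation(annotation)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) abort("annotation does not cover all matrix genes")
  if (is.null(norm)) norm <- lognormalize(counts)
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  is_mito <- !is.na(ann$category) & ann$category == "mitochondrial"
  is_hk <- !is.na(ann$category) & ann$category == "housekeeping"
  mito_ratio <- if (any(is_mito)) {
    Matrix::colSums(counts[is_mito, , drop = FALSE]) / n_umi
  } else rep(0, ncol(counts))
  hk_mean <- if (any(is_hk)) {
    Matrix::colMeans(norm[is_hk, , drop = FALSE])
  } else rep(NA_real_, ncol(counts))
  ds <- rep(NA_real_, ncol(counts))
  if (!is.null(doublet_score)) {
    if (is.data.frame(doublet_score)) {
      ds <- doublet_score$doublet_score[
        match(colnames(counts), doublet_score$cell_barcode)]
    } else {
      ds <- unname(doublet_score[colnames(counts)])
    }
  }
  tibble(
    cell_barcode = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    n_genes = as.integer(n_genes), n_umi = as.numeric(n_umi),
    mito_ratio = as.numeric(mito_ratio), hk_mean = as.numeric(hk_mean),
    doublet_score = ds
  )
}

#' Simulated-doublet nearest-neighbour doublet scores
#'
#' Synthesizes `round(n_sim_ratio * n)` artificial doublets by summing the
#' raw counts of uniformly sampled observed cell pairs, embeds observed and
#' simulated cells into a PCA space fitted on the observed cells (after
#' joint log-normalization and restriction to the most variable genes), and
#' scores each observed cell by the fraction `f` of its `k` nearest
#' neighbours that are simulated. The fraction is rescaled by the
#' simulation prior `rho = n_sim / (n_sim + n)` to
#' `f / (f + (1 - f) * rho / (1 - rho))`, so a score of 0.5 means "as
#' doublet-like as a simulated doublet".
#'
#' @param counts Genes x cells raw count matrix (>= 50 cells).
#' @param n_sim_ratio Simulated doublets per observed cell.
#' @param n_hvg Number of highly variable genes kept.
#' @param n_pcs Number of principal components.
#' @param k Neighbours on the observed-cell graph; `0` (default) means
#'   `round(0.5 * sqrt(n))`.
#' @param adjust_k_joint Scale `k` by `1 + n_sim_ratio` when searching the
#'   joint observed + simulated embedding (default `TRUE`), so the
#'   neighbourhood keeps the same locality it would have among observed
#'   cells alone — the convention of the simulated-doublet method family.
#' @param seed Integer seed (pair sampling).
#' @return A tibble with `cell_barcode` and `doublet_score` in `[0, 1]`.
#' @export
doublet_scores <- function(counts, n_sim_ratio = 2.0, n_hvg = 1000,
                           n_pcs = 20, k = 0, adjust_k_joint = TRUE,
                           seed = 1L) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  n <- ncol(counts)
  if (n < 50) abort("doublet_scores needs at least 50 cells")
  if (k == 0) k <- round(0.5 * sqrt(n))
  if (n < k + 1) abort("fewer cells than k + 1")
  if (adjust_k_joint) k <- round(k * (1 + n_sim_ratio))
  n_sim <- round(n_sim_ratio * n)
  with_seed(seed, {
    pa <- sample.int(n, n_sim, replace = TRUE)
    pb <- sample.int(n, n_sim, replace = TRUE)
  })
  sim <- counts[, pa, drop = FALSE] + counts[, pb, drop = FALSE]
  colnames(sim) <- sprintf("simdbl%06d", seq_len(n_sim))
  joint <- lognormalize(cbind(counts, sim))

  obs_norm <- joint[, seq_len(n), drop = FALSE]
  mu <- Matrix::rowMeans(obs_norm)
  v <- Matrix::rowMeans(obs_norm^2) - mu^2
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(joint)))]
  x <- t(as.matrix(joint[hvg, , drop = FALSE]))  # cells x genes

  obs <- x[seq_len(n), , drop = FALSE]
  n_pcs <- min(n_pcs, ncol(obs), nrow(obs) - 1)
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- sweep(x, 2, pc$center) %*% pc$rotation  # all cells in obs-fitted PCs

  # kNN among all embedded points, excluding self; only observed cells scored
  sq_all <- rowSums(emb^2)
  obs_emb <- emb[seq_len(n), , drop = FALSE]
  f <- numeric(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(obs_emb[idx, , drop = FALSE]^2), sq_all, "+") -
      2 * obs_emb[idx, , drop = FALSE] %*% t(emb)
    for (j in seq_along(idx)) {
      dj <- d2[j, ]
      dj[idx[j]] <- Inf  # exclude self
      nn <- order(dj)[seq_len(k)]
      f[idx[j]] <- mean(nn > n)
    }
  }
  rho <- n_sim / (n_sim + n)
  q <- rho / (1 - rho)
  score <- ifelse(f == 0, 0, f / (f + (1 - f) * q))
  tibble(
    cell_barcode = colnames(counts) %||% as.character(seq_len(n)),
    doublet_score = score
  )
}

#' QC thresholds
#'
#' Container for the cell- and gene-level filtering thresholds. Boundary
#' semantics follow the printed inequalities literally: cells are kept when
#' `n_genes >= min_genes`, `n_genes <= max_genes`, `n_umi >= min_umi`,
#' `mito_ratio < max_mito`, `hk_mean > min_hk` and
#' `doublet_score < doublet_threshold`; genes detected in fewer than
#' `min_cells_per_gene` kept cells are then dropped.
#'
#' @param min_genes,max_genes Detected-gene bounds (default 300, 3000).
#' @param min_umi Minimum UMI count (default 500).
#' @param max_mito Mitochondrial-fraction cap, strict (default 0.2).
#' @param min_hk Housekeeping mean-expression floor, strict (default 0.8).
#' @param min_cells_per_gene Gene detection floor (default 10).
#' @param doublet_threshold Doublet-score cap, strict (default 0.5).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 300, max_genes = 3000, min_umi = 500,
                          max_mito = 0.2, min_hk = 0.8,
                          min_cells_per_gene = 10, doublet_threshold = 0.5) {
  if (min_genes > max_genes) abort("min_genes must be <= max_genes")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_mito = max_mito, min_hk = min_hk,
                 min_cells_per_gene = min_cells_per_gene,
                 doublet_threshold = doublet_threshold),
            class = "qc_thresholds")
}

#' Apply cell- and gene-level QC filters
#'
#' Keeps cells passing all five cell-level predicates (see
#' [qc_thresholds()]), then drops genes detected in fewer than
#' `min_cells_per_gene` of the *kept* cells. A cell can fail several
#' predicates; the report counts each failure reason.
#'
#' When `hk_mean` or `doublet_score` is entirely `NA` (metric not
#' computed), the corresponding filter is skipped.
#'
#' @param counts Genes x cells raw count matrix.
#' @param qc Per-cell table from [cell_qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_filter`: `counts` (filtered matrix),
#'   `cells` (per-cell pass table with per-predicate columns), `report`
#'   (counts per failure reason), `kept_cells`, `kept_genes`,
#'   `thresholds`.
#' @export
apply_qc <- function(counts, qc, thresholds = qc_thresholds()) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  qc <- qc[match(colnames(counts), qc$cell_barcode), ]
  if (anyNA(qc$cell_barcode)) abort("qc table does not cover all cells")
  th <- thresholds
  pass_genes <- qc$n_genes >= th$min_genes & qc$n_genes <= th$max_genes
  pass_umi <- qc$n_umi >= th$min_umi
  pass_mito <- qc$mito_ratio < th$max_mito
  pass_hk <- if (all(is.na(qc$hk_mean))) rep(TRUE, nrow(qc))
             else qc$hk_mean > th$min_hk
  pass_dbl <- if (all(is.na(qc$doublet_score))) rep(TRUE, nrow(qc))
              else qc$doublet_score < th$doublet_threshold
  keep_cell <- pass_genes & pass_umi & pass_mito & pass_hk & pass_dbl

  kept <- counts[, keep_cell, drop = FALSE]
  detected <- Matrix::rowSums(kept > 0)
  keep_gene <- detected >= th$min_cells_per_gene
  out <- kept[keep_gene, , drop = FALSE]

  cells <- tibble(
    cell_barcode = qc$cell_barcode,
    pass_n_genes = pass_genes, pass_n_umi = pass_umi,
    pass_mito = pass_mito, pass_hk = pass_hk, pass_doublet = pass_dbl,
    pass = keep_cell
  )
  report <- tibble(
    reason = c("n_genes_out_of_range", "low_umi", "high_mito", "low_hk",
               "doublet", "cells_kept", "cells_dropped", "genes_dropped",
               "genes_kept"),
    n = c(sum(!pass_genes), sum(!pass_umi), sum(!pass_mito), sum(!pass_hk),
          sum(!pass_dbl), sum(keep_cell), sum(!keep_cell), sum(!keep_gene),
          sum(keep_gene))
  )
  structure(list(counts = out, cells = cells, report = report,
                 kept_cells = colnames(out) %||% character(0),
                 kept_genes = rownames(out) %||% character(0),
                 thresholds = thresholds),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat("<qc_filter> kept ", length(x$kept_cells), " cells / ",
      length(x$kept_genes), " genes\n", sep = "")
  print(x$report)
  invisible(x)
}
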