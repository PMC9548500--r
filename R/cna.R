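#' Parameters for expression-based CNA inference
#'
#' Defaults follow the established conventions of moving-average CNA
#' inference from scRNA-seq expression: genes below a mean-expression
#' cutoff are excluded, reference-centered values are clipped symmetrically
#' and smoothed along the genome with a pyramidal (triangular) window that
#' never crosses a chromosome boundary.
#'
#' @param min_mean_expr Gene-inclusion cutoff on mean normalized
#'   expression over all cells (default 0.1).
#' @param clip Symmetric cap on reference-centered values (default 3).
#' @param window Odd window size in genes (default 101).
#' @param weights `"pyramidal"` (weights `1, 2, ..., ceiling(window/2),
#'   ..., 2, 1`, renormalized; truncated and renormalized at chromosome
#'   edges) or `"uniform"`.
#' @return A list of class `cna_params`.
#' @export
cna_params <- function(min_mean_expr = 0.1, clip = 3.0, window = 101L,
                       weights = c("pyramidal", "uniform")) {
  weights <- match.arg(weights)
  if (window < 1 || window %% 2 == 0) abort("window must be odd and >= 1")
  if (clip <= 0) abort("clip must be positive")
  structure(list(min_mean_expr = min_mean_expr, clip = clip,
                 window = as.integer(window), weights = weights),
            class = "cna_params")
}

# Column medians without apply()'s aperm overhead.
col_medians <- function(x) {
  n <- nrow(x)
  h <- (n + 1L) %/% 2L
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (n %% 2L == 1L) sort.int(v, partial = h)[h]
    else {
      s <- sort.int(v, partial = c(h, h + 1L))
      (s[h] + s[h + 1L]) / 2
    }
  }, numeric(1))
}

# Column-wise cumulative sums with a zero row prepended, computed by a
# row recurrence: few R-level iterations, each vectorized over cells —
# much faster than apply(x, 2, cumsum) for wide matrices.
cumsum_rows <- function(x) {
  out <- matrix(0, nrow(x) + 1L, ncol(x))
  for (i in seq_len(nrow(x))) out[i + 1L, ] <- out[i, ] + x[i, ]
  out
}

# Running-sum smoother along rows of a dense genes x cells block.
# A centered triangular window of half-width h equals the convolution of
# two uniform windows of length L = h + 1; computing it as two running
# sums over a zero-padded vector and dividing by the same operator applied
# to a vector of ones yields exactly the truncated, renormalized window at
# the chromosome edges, in O(genes x cells).
smooth_block <- function(x, window, weights) {
  m <- nrow(x)
  if (window == 1) return(x)
  if (weights == "uniform") {
    h <- (window - 1L) %/% 2L
    cs <- cumsum_rows(x)                            # cs[i + 1, ] = sum x[1..i]
    hi <- pmin(seq_len(m) + h, m) + 1L
    lo <- pmax(seq_len(m) - h - 1L, 0L) + 1L
    num <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
    den <- (pmin(seq_len(m) + h, m) - pmax(seq_len(m) - h, 1L) + 1L)
    return(num / den)
  }
  L <- (window + 1L) %/% 2L                         # triangle peak height
  tri2 <- function(mat) {
    mm <- nrow(mat)
    cs <- cumsum_rows(mat)
    k <- seq.int(2L - L, mm)                        # extended window starts
    u1 <- cs[pmin(k + L - 1L, mm) + 1L, , drop = FALSE] -
      cs[pmax(k - 1L, 0L) + 1L, , drop = FALSE]
    cu <- cumsum_rows(u1)                           # over the k grid
    pos <- function(i) i - (2L - L) + 1L
    cu[pos(seq_len(mm)) + 1L, , drop = FALSE] -
      cu[pos(seq_len(mm) - L) + 1L, , drop = FALSE]
  }
  num <- tri2(x)
  den <- tri2(matrix(1, nrow = m, ncol = 1))
  num / as.vector(den)
}

#' Infer per-cell CNA profiles from normalized expression
#'
#' Deterministic pipeline using non-malignant cells as the copy-neutral
#' reference: (1) drop genes whose mean normalized expression over all
#' included cells is below `min_mean_expr`; (2) center each gene on its
#' reference-cell mean; (3) clip to `[-clip, clip]`; (4) order genes by
#' (chromosome, start) and smooth each cell's vector within each
#' chromosome with the configured moving window; (5) subtract each cell's
#' median across genes; (6) re-center each gene on the post-smoothing
#' reference mean, so reference cells average to exactly zero.
#'
#' @param norm Normalized genes x cells matrix from [lognormalize()].
#' @param annotation Gene annotation covering all matrix genes.
#' @param reference_cells,query_cells Disjoint character vectors of cell
#'   barcodes (columns of `norm`); at least 2 reference cells.
#' @param params A [cna_params()] object.
#' @return An object of class `cna_matrix`: list with `cna` (dense genes x
#'   cells matrix of smoothed residuals, 0 = copy-neutral, genes in
#'   genomic order), `genes` (tibble: `gene_id`, `chromosome`, `start`),
#'   `reference_cells`, `query_cells`, `params`.
#' @export
infer_cna_matrix <- function(norm, annotation, reference_cells, query_cells,
                             params = cna_params()) {
  stopifnot(inherits(params, "cna_params"))
  check_annotation(annotation)
  if (length(intersect(reference_cells, query_cells)) > 0) {
    abort("reference and query cell sets must be disjoint")
  }
  if (length(reference_cells) < 2) abort("need at least 2 reference cells")
  cells <- intersect(colnames(norm), c(reference_cells, query_cells))
  missing <- setdiff(c(reference_cells, query_cells), colnames(norm))
  if (length(missing) > 0) {
    abort(paste0("cells not in matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- if (identical(cells, colnames(norm))) norm
       else norm[, cells, drop = FALSE]
  ann <- annotation[match(rownames(x), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) abort("annotation does not cover all matrix genes")

  # (1) gene inclusion on mean normalized expression over all cells
  keep <- Matrix::rowMeans(x) >= params$min_mean_expr
  if (!any(keep)) abort("no genes pass min_mean_expr")
  ann <- ann[keep, , drop = FALSE]

  # (4a) genomic order (chromosome, start, gene_id); one dense subset
  # combines the gene filter and the reorder
  ann_ord <- order_annotation(ann)
  x <- as.matrix(x)[match(ann_ord$gene_id, rownames(x)), , drop = FALSE]

  is_ref <- colnames(x) %in% reference_cells
  # (2) reference centering
  x <- x - rowMeans(x[, is_ref, drop = FALSE])
  # (3) clipping
  if (is.finite(params$clip)) {
    dm <- dimnames(x)
    x <- pmin.int(pmax.int(x, -params$clip), params$clip)
    dim(x) <- c(nrow(ann_ord), length(cells)); dimnames(x) <- dm
  }
  # (4b) within-chromosome smoothing
  for (chr in unique(ann_ord$chromosome)) {
    rows <- which(ann_ord$chromosome == chr)
    x[rows, ] <- smooth_block(x[rows, , drop = FALSE],
                              params$window, params$weights)
  }
  # (5) per-cell median correction (column-wise, avoiding sweep/aperm)
  x <- x - matrix(col_medians(x), nrow(x), ncol(x), byrow = TRUE)
  # (6) post-smoothing reference re-centering
  x <- x - rowMeans(x[, is_ref, drop = FALSE])

  structure(
    list(cna = x,
         genes = tibble(gene_id = ann_ord$gene_id,
                        chromosome = ann_ord$chromosome,
                        start = ann_ord$start),
         reference_cells = intersect(cells, reference_cells),
         query_cells = intersect(cells, query_cells),
         params = params),
    class = "cna_matrix"
  )
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat("<cna_matrix> ", nrow(x$cna), " genes x ", ncol(x$cna), " cells (",
      length(x$reference_cells), " reference)\n", sep = "")
  invisible(x)
}

#' Mean CNA profiles per group
#'
#' Averages smoothed per-cell CNA residuals within groups (typically one
#' group per tumor, or per tumor x malignant cluster). The resulting
#' per-group vectors are the profiles whose pairwise Pearson correlation
#' is the clonality statistic.
#'
#' @param cna A [infer_cna_matrix()] result.
#' @param groups Tibble with columns `cell_barcode` and `group` (or a
#'   named character vector, names = barcodes). Typically restricted to
#'   malignant cells by the caller.
#' @return An object of class `cna_profiles`: list with `profiles` (genes
#'   x groups matrix), `genes`, `sizes` (cells per group).
#' @export
mean_cna_profiles <- function(cna, groups) {
  stopifnot(inherits(cna, "cna_matrix"))
  if (!is.data.frame(groups)) {
    groups <- tibble(cell_barcode = names(groups),
                     group = unname(groups))
  }
  missing <- setdiff(groups$cell_barcode, colnames(cna$cna))
  if (length(missing) > 0) {
    abort(paste0("grouped cells not present in CNA matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  labels <- if (is.factor(groups$group)) levels(groups$group)
            else unique(groups$group)
  prof <- vapply(labels, function(g) {
    cells <- groups$cell_barcode[groups$group == g]
    if (length(cells) == 0) abort(paste0("empty group: ", g))
    rowMeans(cna$cna[, cells, drop = FALSE])
  }, numeric(nrow(cna$cna)))
  colnames(prof) <- labels
  structure(
    list(profiles = prof, genes = cna$genes,
         sizes = stats::setNames(
           as.integer(table(groups$group)[labels]), labels)),
    class = "cna_profiles"
  )
}

#' @export
print.cna_profiles <- function(x, ...) {
  cat("<cna_profiles> ", ncol(x$profiles), " group(s) over ",
      nrow(x$profiles), " genes\n", sep = "")
  invisible(x)
}
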