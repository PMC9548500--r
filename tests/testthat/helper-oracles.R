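# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately written straight-line / brute-force and
# never calls the package's own implementation of the checked step.

# Straight-line re-implementation of the CNA inference steps 1-6
# (explicit loops, explicit window weights, truncated + renormalized at
# chromosome edges). `norm` is a dense genes x cells matrix with dimnames.
oracle_cna <- function(norm, annotation, reference_cells, query_cells,
                       min_mean_expr = 0.1, clip = 3, window = 101,
                       weights = "pyramidal") {
  cells <- c(reference_cells, query_cells)
  x <- as.matrix(norm[, cells, drop = FALSE])
  ann <- annotation[match(rownames(x), annotation$gene_id), ]
  keep <- rowMeans(x) >= min_mean_expr
  x <- x[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  # order genes: numeric chromosomes first, then others, by start then id
  chr <- ann$chromosome
  num <- suppressWarnings(as.numeric(chr))
  ord <- order(is.na(num), num, chr, ann$start, ann$gene_id)
  x <- x[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]
  ref <- colnames(x) %in% reference_cells
  for (g in seq_len(nrow(x))) x[g, ] <- x[g, ] - mean(x[g, ref])
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  h <- (window - 1) / 2
  w_full <- if (weights == "pyramidal") {
    c(seq_len(h + 1), rev(seq_len(h)))
  } else rep(1, window)
  sm <- x
  for (chrom in unique(ann$chromosome)) {
    rows <- which(ann$chromosome == chrom)
    for (ci in seq_len(ncol(x))) {
      v <- x[rows, ci]
      out <- numeric(length(v))
      for (i in seq_along(v)) {
        lo <- max(1, i - h); hi <- min(length(v), i + h)
        w <- w_full[(lo - i + h + 1):(hi - i + h + 1)]
        out[i] <- sum(v[lo:hi] * w) / sum(w)
      }
      sm[rows, ci] <- out
    }
  }
  for (ci in seq_len(ncol(sm))) sm[, ci] <- sm[, ci] - median(sm[, ci])
  for (g in seq_len(nrow(sm))) sm[g, ] <- sm[g, ] - mean(sm[g, ref])
  list(cna = sm, genes = ann)
}

# Area under the ROC curve via the rank-sum identity.
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Upper-tail hypergeometric P(X >= k) by explicit mass summation.
oracle_hyper_upper <- function(k, M, K, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}

# Benjamini-Hochberg step-up, hand-coded.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hand-coded Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small two-tumor-plus-references simulation used by several tests.
small_sim <- function(seed = 1, n_epi = 120, n_ref = 80,
                      multiplier = 2, chrom = "1",
                      genes_per_chromosome = 60, n_chromosomes = 4) {
  genome <- make_genome(n_chromosomes, genes_per_chromosome,
                        n_mito = 5, n_housekeeping = 15, seed = seed)
  clones <- tibble::tibble(clone_id = "c1", chromosome = chrom,
                           start = 1L, end = 10000000L,
                           multiplier = multiplier)
  plans <- dplyr::bind_rows(
    cell_plan("S1", "epithelial", n_epi, clone_id = "c1"),
    cell_plan("S1", "T_cell", n_ref)
  )
  simulate_tumor_counts(genome, clones, plans, seed = seed)
}
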