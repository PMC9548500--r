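toy_counts <- function(values, genes, cells) {
  m <- Matrix::Matrix(matrix(values, nrow = length(genes),
                             dimnames = list(genes, cells)), sparse = TRUE)
  methods::as(m, "CsparseMatrix")
}

test_that("lognormalize matches the printed formula", {
  m <- toy_counts(c(1, 9999, 5, 4995), c("g1", "g2"), c("c1", "c2"))
  norm <- lognormalize(m)
  # count 1, total 10,000 -> log(2); count 5, total 5,000 -> log(11)
  expect_equal(norm["g1", "c1"], log(2), tolerance = 1e-12)
  expect_equal(norm["g1", "c2"], log(11), tolerance = 1e-12)

  m0 <- toy_counts(c(0, 10, 3, 7), c("g1", "g2"), c("c1", "c2"))
  expect_identical(lognormalize(m0)["g1", "c1"], 0)  # zero stays exactly 0

  norm2 <- lognormalize(m, log_base = "two")
  expect_equal(norm2["g1", "c1"], log2(2), tolerance = 1e-12)

  mz <- toy_counts(c(0, 0, 1, 1), c("g1", "g2"), c("dead", "alive"))
  expect_error(lognormalize(mz), "dead")
})

test_that("cell_qc_metrics computes the toy column by hand", {
  ann <- tibble::tibble(
    gene_id = c("geneA", "geneB", "mito1", "hk1"),
    chromosome = c("1", "1", "MT", "2"),
    start = c(1L, 100L, 1L, 1L), end = c(50L, 150L, 50L, 50L),
    category = c("ordinary", "ordinary", "mitochondrial", "housekeeping"))
  m <- toy_counts(c(2, 0, 1, 0, 1, 1, 1, 1),
                  c("geneA", "geneB", "mito1", "hk1"), c("c1", "c2"))
  qc <- cell_qc_metrics(m, ann)
  expect_equal(qc$n_genes[1], 2L)
  expect_equal(qc$n_umi[1], 3)
  expect_equal(qc$mito_ratio[1], 1 / 3)
  expect_equal(qc$hk_mean[1], 0)          # all-zero housekeeping -> 0
  expect_equal(qc$n_genes[2], 4L)         # every gene expressed -> bound
})

test_that("apply_qc follows the printed boundary semantics", {
  n_genes_total <- 3000
  mk_cell <- function(n_genes, n_umi, mito, hk_high) {
    v <- numeric(n_genes_total)
    # genes 1..n_genes expressed; gene 1 is mito, gene 2 is housekeeping
    stopifnot(n_genes >= 2)
    v[seq_len(n_genes)] <- 1
    extra <- n_umi - n_genes - round(mito * n_umi) + 1
    v[1] <- round(mito * n_umi)
    v[2] <- if (hk_high) extra else 1
    v[3] <- v[3] + max(0, n_umi - sum(v))
    v
  }
  ann <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n_genes_total)),
    chromosome = c("MT", rep("1", n_genes_total - 1)),
    start = seq_len(n_genes_total) * 10L,
    end = seq_len(n_genes_total) * 10L + 5L,
    category = c("mitochondrial", "housekeeping",
                 rep("ordinary", n_genes_total - 2)))
  # boundary cell: exactly 300 genes, 500 UMI, mito 0.19, hk high, score 0
  cells <- cbind(
    boundary = mk_cell(300, 500, 0.19, TRUE),
    mito_exact = mk_cell(400, 800, 0.20, TRUE),   # mito == 0.2 -> dropped
    ok = mk_cell(400, 900, 0.05, TRUE)
  )
  rownames(cells) <- ann$gene_id
  m <- methods::as(Matrix::Matrix(cells, sparse = TRUE), "CsparseMatrix")
  qc <- cell_qc_metrics(m, ann)
  qc$doublet_score <- c(0, 0, 0)
  filt <- apply_qc(m, qc, qc_thresholds(min_cells_per_gene = 0))
  expect_true("boundary" %in% filt$kept_cells)
  expect_false("mito_exact" %in% filt$kept_cells)
  expect_true("ok" %in% filt$kept_cells)
  expect_equal(qc$mito_ratio[2], 0.2, tolerance = 1e-12)
})

test_that("apply_qc equals brute-force predicates on a toy table", {
  # six cells, each failing exactly one predicate (or none)
  qc <- tibble::tibble(
    cell_barcode = sprintf("c%d", 1:7),
    n_genes = c(299L, 3001L, 500L, 500L, 500L, 500L, 500L),
    n_umi = c(1000, 1000, 499, 1000, 1000, 1000, 1000),
    mito_ratio = c(0.1, 0.1, 0.1, 0.25, 0.1, 0.1, 0.1),
    hk_mean = c(1.5, 1.5, 1.5, 1.5, 0.7, 1.5, 1.5),
    doublet_score = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.9, 0.1))
  genes <- sprintf("g%02d", 1:12)
  set.seed(1)
  m <- toy_counts(rpois(12 * 7, 5) + 1, genes, qc$cell_barcode)
  th <- qc_thresholds(min_cells_per_gene = 2)
  filt <- apply_qc(m, qc, th)
  brute <- qc$cell_barcode[
    qc$n_genes >= 300 & qc$n_genes <= 3000 & qc$n_umi >= 500 &
      qc$mito_ratio < 0.2 & qc$hk_mean > 0.8 & qc$doublet_score < 0.5]
  expect_identical(filt$kept_cells, brute)
  # gene predicate: detected in >= 2 kept cells (all genes qualify here)
  kept <- m[, brute, drop = FALSE]
  expect_identical(filt$kept_genes, rownames(kept)[
    Matrix::rowSums(kept > 0) >= 2])
})

test_that("apply_qc is idempotent and kept cells satisfy every predicate", {
  sim <- small_sim(seed = 4, n_epi = 100, n_ref = 80)
  qc <- cell_qc_metrics(sim$counts, sim$annotation)
  th <- qc_thresholds(min_genes = 10, max_genes = 10000, min_umi = 100,
                      min_cells_per_gene = 3)
  f1 <- apply_qc(sim$counts, qc, th)
  f2 <- apply_qc(f1$counts, qc[qc$cell_barcode %in% f1$kept_cells, ], th)
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
  kept_qc <- qc[qc$cell_barcode %in% f1$kept_cells, ]
  expect_true(all(kept_qc$n_genes >= th$min_genes &
                    kept_qc$n_genes <= th$max_genes &
                    kept_qc$n_umi >= th$min_umi &
                    kept_qc$mito_ratio < th$max_mito &
                    kept_qc$hk_mean > th$min_hk))
})

test_that("metric filters pass nearly all typical simulated cells", {
  # calibration: generous baselines, no doublets; the four metric
  # predicates at the printed defaults keep >= 99% of cells
  genome <- make_genome(8, 250, n_mito = 13, n_housekeeping = 60, seed = 6)
  plans <- cell_plan("S1", c("epithelial", "T_cell"), c(500, 300))
  sim <- simulate_tumor_counts(genome, NULL, plans, seed = 6)
  qc <- cell_qc_metrics(sim$counts, sim$annotation)
  filt <- apply_qc(sim$counts, qc, qc_thresholds())
  expect_gte(mean(filt$cells$pass), 0.99)
})

test_that("doublet scores: bookkeeping, symmetry and rescaling", {
  set.seed(2)
  m <- toy_counts(rep(rpois(30, 8), 60), sprintf("g%02d", 1:30),
                  sprintf("c%02d", 1:60))
  sc <- doublet_scores(m, n_hvg = 30, n_pcs = 5, seed = 1)
  expect_equal(length(unique(round(sc$doublet_score, 12))), 1) # exchangeable
  expect_true(all(sc$doublet_score >= 0 & sc$doublet_score <= 1))
  expect_error(doublet_scores(m[, 1:10]), "at least 50")
})

test_that("doublet scores separate true heterotypic doublets", {
  genome <- make_genome(3, 100, 0, 0, seed = 8)
  plans <- cell_plan("S1", c("A", "B"), c(150, 150), doublet_fraction = 0.1)
  sim <- simulate_tumor_counts(genome, NULL, plans,
                               marker_genes_per_class = 60,
                               marker_boost = 8, seed = 8)
  sc <- doublet_scores(sim$counts, n_hvg = 200, n_pcs = 10, seed = 8)
  truth <- sim$truth$is_doublet[match(sc$cell_barcode,
                                      sim$truth$cell_barcode)]
  expect_gte(auroc(sc$doublet_score, truth), 0.85)
})
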