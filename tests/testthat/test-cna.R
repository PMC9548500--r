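dense_named <- function(values, genes, cells) {
  matrix(values, nrow = length(genes), dimnames = list(genes, cells))
}

toy_annotation <- function(chroms, gene_ids = NULL) {
  n <- length(chroms)
  tibble::tibble(
    gene_id = gene_ids %||% sprintf("g%02d", seq_len(n)),
    chromosome = chroms,
    start = as.integer(ave(seq_len(n), chroms, FUN = seq_along) * 100L),
    end = as.integer(ave(seq_len(n), chroms, FUN = seq_along) * 100L + 10L))
}

test_that("exact-copy-of-reference query infers exactly zero CNA", {
  ann <- toy_annotation(rep("1", 5))
  # reference cells chosen so the centered residuals have median 0 per cell
  ref1 <- c(1, 2, 3, 4, 5); ref2 <- c(5, 4, 3, 2, 1)
  query <- (ref1 + ref2) / 2
  m <- dense_named(c(ref1, ref2, query), ann$gene_id, c("r1", "r2", "q"))
  res <- infer_cna_matrix(m, ann, c("r1", "r2"), "q",
                          cna_params(min_mean_expr = 0, window = 1))
  expect_equal(unname(res$cna[, "q"]), rep(0, 5), tolerance = 1e-14)
  # reference self-centering holds for every gene
  expect_equal(unname(rowMeans(res$cna[, c("r1", "r2")])), rep(0, 5),
               tolerance = 1e-14)
})

test_that("window = 1 makes smoothing the identity", {
  set.seed(10)
  ann <- toy_annotation(rep(c("1", "2"), each = 6))
  m <- dense_named(rnorm(12 * 5, 2, 1), ann$gene_id, sprintf("c%d", 1:5))
  res <- infer_cna_matrix(m, ann, c("c1", "c2"), c("c3", "c4", "c5"),
                          cna_params(min_mean_expr = 0, clip = Inf,
                                     window = 1, weights = "uniform"))
  # manual: center on reference, subtract per-cell median, re-center
  x <- m - rowMeans(m[, c("c1", "c2")])
  x <- sweep(x, 2, apply(x, 2, median))
  x <- x - rowMeans(x[, c("c1", "c2")])
  expect_equal(res$cna[rownames(x), ], x[, colnames(res$cna)],
               tolerance = 1e-14)
})

test_that("pipeline matches the straight-line oracle", {
  # 5-gene, 2-cell hand-constructed instance, window 3 pyramidal
  ann5 <- toy_annotation(rep("1", 5))
  m5 <- dense_named(c(0.5, 2.0, 1.0, 3.0, 0.2,
                      1.5, 0.1, 2.5, 0.8, 1.2,
                      2.2, 1.1, 0.3, 1.9, 0.7),
                    ann5$gene_id, c("r1", "r2", "q1"))
  res5 <- infer_cna_matrix(m5, ann5, c("r1", "r2"), "q1",
                           cna_params(min_mean_expr = 0.1, clip = 3,
                                      window = 3))
  or5 <- oracle_cna(m5, ann5, c("r1", "r2"), "q1",
                    min_mean_expr = 0.1, clip = 3, window = 3)
  expect_equal(res5$cna, or5$cna[, colnames(res5$cna)], tolerance = 1e-12)

  # randomized multi-chromosome instances, both weight schemes,
  # including clipping activity and the low-expression gene filter
  for (seed in 1:3) {
    set.seed(seed)
    ann <- toy_annotation(sample(rep(c("2", "10", "MT"), times = c(13, 9, 4))))
    m <- dense_named(abs(rnorm(26 * 7, 1.2, 1.5)), ann$gene_id,
                     sprintf("c%d", 1:7))
    for (w in c("pyramidal", "uniform")) {
      res <- infer_cna_matrix(m, ann, c("c1", "c2", "c3"),
                              c("c4", "c5", "c6", "c7"),
                              cna_params(min_mean_expr = 0.4, clip = 0.8,
                                         window = 5, weights = w))
      or <- oracle_cna(m, ann, c("c1", "c2", "c3"),
                       c("c4", "c5", "c6", "c7"),
                       min_mean_expr = 0.4, clip = 0.8, window = 5,
                       weights = w)
      expect_equal(res$cna, or$cna[, colnames(res$cna)], tolerance = 1e-12)
      expect_identical(res$genes$gene_id, or$genes$gene_id)
    }
  }
})

test_that("output is equivariant to input gene and cell order", {
  set.seed(12)
  ann <- toy_annotation(rep(c("1", "2"), each = 10))
  m <- dense_named(abs(rnorm(20 * 6, 1, 1)), ann$gene_id,
                   sprintf("c%d", 1:6))
  p <- cna_params(min_mean_expr = 0, window = 3)
  res <- infer_cna_matrix(m, ann, c("c1", "c2"), c("c3", "c4", "c5", "c6"), p)
  gp <- sample(nrow(m)); cp <- sample(ncol(m))
  res_p <- infer_cna_matrix(m[gp, cp], ann[gp, ],
                            c("c1", "c2"), c("c3", "c4", "c5", "c6"), p)
  expect_equal(res$cna, res_p$cna[, colnames(res$cna)], tolerance = 1e-12)
})

test_that("mean profiles average rows and validate groups", {
  set.seed(13)
  ann <- toy_annotation(rep("1", 8))
  m <- dense_named(abs(rnorm(8 * 6, 1, 1)), ann$gene_id, sprintf("c%d", 1:6))
  cna <- infer_cna_matrix(m, ann, c("c1", "c2"), c("c3", "c4", "c5", "c6"),
                          cna_params(min_mean_expr = 0, window = 3))
  single <- mean_cna_profiles(cna, tibble::tibble(cell_barcode = "c3",
                                                  group = "G"))
  expect_equal(unname(single$profiles[, "G"]), unname(cna$cna[, "c3"]))
  twin <- mean_cna_profiles(
    cna, tibble::tibble(cell_barcode = c("c3", "c3"), group = c("A", "B")))
  expect_equal(twin$profiles[, "A"], twin$profiles[, "B"])
  expect_error(
    mean_cna_profiles(cna, tibble::tibble(
      cell_barcode = factor("c3"),
      group = factor("A", levels = c("A", "GHOST")))),
    "GHOST")
  expect_error(
    mean_cna_profiles(cna, tibble::tibble(cell_barcode = "zz", group = "A")),
    "zz")
})

test_that("segment gains are recovered in group mean profiles", {
  sim <- small_sim(seed = 14, n_epi = 150, n_ref = 100, multiplier = 2,
                   chrom = "2")
  norm <- lognormalize(sim$counts)
  ref <- sim$truth$cell_barcode[sim$truth$cell_class == "T_cell"]
  qry <- sim$truth$cell_barcode[sim$truth$cell_class == "epithelial"]
  cna <- infer_cna_matrix(norm, sim$annotation, ref, qry,
                          cna_params(window = 31))
  prof <- mean_cna_profiles(cna, tibble::tibble(cell_barcode = qry,
                                                group = "tumor"))
  inside <- prof$genes$chromosome == "2"
  expect_gt(mean(prof$profiles[inside, "tumor"]),
            mean(prof$profiles[!inside, "tumor"]))
  expect_gt(mean(prof$profiles[inside, "tumor"]), 0)
})

test_that("inferred segment CNA is monotone in the true copy multiplier", {
  seg_means <- vapply(c(0.5, 1, 1.5, 2), function(mult) {
    sim <- small_sim(seed = 15, n_epi = 120, n_ref = 80,
                     multiplier = mult, chrom = "3")
    norm <- lognormalize(sim$counts)
    ref <- sim$truth$cell_barcode[sim$truth$cell_class == "T_cell"]
    qry <- sim$truth$cell_barcode[sim$truth$cell_class == "epithelial"]
    cna <- infer_cna_matrix(norm, sim$annotation, ref, qry,
                            cna_params(window = 31))
    prof <- mean_cna_profiles(cna, tibble::tibble(cell_barcode = qry,
                                                  group = "t"))
    mean(prof$profiles[prof$genes$chromosome == "3", "t"])
  }, numeric(1))
  expect_true(all(diff(seg_means) > 0))
})

test_that("input validation catches bad reference sets", {
  ann <- toy_annotation(rep("1", 5))
  m <- dense_named(abs(rnorm(5 * 4, 1, 1)), ann$gene_id, sprintf("c%d", 1:4))
  expect_error(infer_cna_matrix(m, ann, "c1", c("c2", "c3"), cna_params()),
               "at least 2")
  expect_error(infer_cna_matrix(m, ann, c("c1", "c2"), c("c2", "c3"),
                                cna_params()), "disjoint")
  expect_error(cna_params(window = 4), "odd")
})
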