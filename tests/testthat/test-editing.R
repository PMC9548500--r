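site_c2t <- site_spec("DDOST_558C>U", "C", "T")

reads_tbl <- function(umi, barcode, base, qual = 30L, sample = "S1") {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(umi)), umi = umi,
    cell_barcode = barcode, sample_id = sample, base = base,
    base_quality = as.integer(qual))
}

test_that("UMI-majority collapse and call thresholds", {
  # cell with UMIs {C, C, T} -> 1 alt UMI -> edited at min_alt_umis = 1
  rd <- reads_tbl(c("u1", "u2", "u3"), "cellA", c("C", "C", "T"))
  calls <- call_site_editing(rd, site_c2t)
  expect_equal(as.character(calls$call), "edited")
  expect_equal(calls$n_umis, 3L)
  expect_equal(calls$n_alt_umis, 1L)

  # the same cell needs 2 alt UMIs -> unedited
  calls2 <- call_site_editing(rd, site_c2t, min_alt_umis = 2)
  expect_equal(as.character(calls2$call), "unedited")

  # a tie UMI {C, T} as the only UMI -> discarded -> unobserved
  tie <- reads_tbl(c("u1", "u1"), "cellB", c("C", "T"))
  expect_equal(as.character(call_site_editing(tie, site_c2t)$call),
               "unobserved")

  # low-quality and N reads are discarded before collapse
  lowq <- reads_tbl(c("u1", "u2", "u3"), "cellC", c("T", "T", "N"),
                    qual = c(10L, 30L, 30L))
  c3 <- call_site_editing(lowq, site_c2t)
  expect_equal(c3$n_umis, 1L)
  expect_equal(as.character(c3$call), "edited")

  bad <- reads_tbl("u1", "cellD", "X")
  expect_error(call_site_editing(bad, site_c2t), "r001")
  expect_error(site_spec("s", "C", "C"), "differ")
})

test_that("majority within a UMI suppresses a minority error read", {
  rd <- reads_tbl(c("u1", "u1", "u1"), "cellA", c("C", "C", "T"))
  calls <- call_site_editing(rd, site_c2t)
  expect_equal(calls$n_alt_umis, 0L)
  expect_equal(as.character(calls$call), "unedited")
})

test_that("calls are invariant to read order", {
  set.seed(50)
  rd <- reads_tbl(sample(c("u1", "u2", "u3"), 40, TRUE),
                  sample(c("ca", "cb"), 40, TRUE),
                  sample(c("C", "T"), 40, TRUE),
                  qual = sample(15:40, 40, TRUE))
  shuffled <- rd[sample(nrow(rd)), ]
  shuffled$read_id <- rd$read_id  # ids travel with rows; rename for equality
  a <- call_site_editing(rd, site_c2t)
  b <- call_site_editing(shuffled, site_c2t)
  expect_equal(a[, c("cell_barcode", "n_umis", "n_alt_umis", "call")],
               b[, c("cell_barcode", "n_umis", "n_alt_umis", "call")])
})

test_that("raising thresholds never increases edited cells", {
  set.seed(51)
  truth <- tibble::tibble(cell_barcode = sprintf("c%03d", 1:150),
                          sample_id = rep(c("S1", "S2"), 75),
                          cell_class = rep(c("epithelial", "T_cell"), each = 75))
  rd <- simulate_editing_reads(
    truth, site_c2t,
    edited_classes = tibble::tibble(sample_id = "S1",
                                    cell_class = "epithelial"),
    edit_rate = 0.6, coverage_mean = 6, error_rate = 0.05, seed = 51)
  n_edited <- function(bq, alt) {
    sum(call_site_editing(rd, site_c2t, min_base_quality = bq,
                          min_alt_umis = alt)$call == "edited")
  }
  for (alt in 1:3) {
    e <- vapply(c(0, 20, 30, 37), n_edited, numeric(1), alt = alt)
    expect_true(all(diff(e) <= 0))
  }
  for (bq in c(0, 25, 35)) {
    e <- vapply(1:4, function(a) n_edited(bq, a), numeric(1))
    expect_true(all(diff(e) <= 0))
  }
})

test_that("error-free simulation agrees exactly with generator truth", {
  set.seed(52)
  truth <- tibble::tibble(cell_barcode = sprintf("c%03d", 1:200),
                          sample_id = "S1",
                          cell_class = rep(c("epithelial", "B_cell"), 100))
  rd <- simulate_editing_reads(
    truth, site_c2t,
    edited_classes = tibble::tibble(sample_id = "S1",
                                    cell_class = "epithelial"),
    edit_rate = 0.5, coverage_mean = 4, error_rate = 0, seed = 52)
  umi_truth <- attr(rd, "umi_truth")
  calls <- call_site_editing(rd, site_c2t, min_base_quality = 0)
  merged <- merge(calls, umi_truth, by = "cell_barcode")
  expect_equal(merged$n_alt_umis.x, merged$n_alt_umis.y)
  expect_equal(merged$call == "edited", merged$n_alt_umis.y >= 1)
  # cells with zero reads are unobserved, never unedited
  uncovered <- setdiff(truth$cell_barcode, calls$cell_barcode)
  expect_equal(sort(uncovered),
               sort(umi_truth$cell_barcode[umi_truth$n_umis == 0]))
})

test_that("summary fractions, empty strata and class collapse", {
  calls <- tibble::tibble(
    cell_barcode = sprintf("c%02d", 1:12),
    sample_id = "S1",
    n_reads = 2L, n_umis = c(rep(1L, 10), 0L, 0L),
    n_alt_umis = c(rep(1L, 3), rep(0L, 9)),
    call = factor(c(rep("edited", 3), rep("unedited", 7),
                    rep("unobserved", 2)),
                  levels = c("edited", "unedited", "unobserved")))
  meta <- tibble::tibble(cell_barcode = sprintf("c%02d", 1:12),
                         sample_id = "S1",
                         cell_class = c(rep("epi", 10), "dark", "dark"))
  summ <- summarize_editing(calls, meta)
  epi <- summ[summ$cell_class == "epi", ]
  expect_equal(epi$n_cells_covered, 10)
  expect_equal(epi$n_cells_edited, 3)
  expect_equal(epi$edited_fraction, 0.3)
  dark <- summ[summ$cell_class == "dark", ]
  expect_true(is.na(dark$edited_fraction))     # zero covered -> missing

  collapsed <- summarize_editing(
    calls, meta, class_collapse = c(epi = "Epi", dark = "non-Epi"))
  expect_setequal(collapsed$cell_class, c("Epi", "non-Epi"))
  expect_error(summarize_editing(calls, meta[-1, ]), "c01")
  expect_error(summarize_editing(calls, meta, class_collapse = c(epi = "Epi")),
               "dark")
})

test_that("edited stratum dominates end-to-end", {
  classes <- c("epithelial", "T_cell")
  truth <- tidyr::expand_grid(sample_id = c("S1", "S2", "S3"),
                              cell_class = classes,
                              idx = 1:300) |>
    dplyr::mutate(cell_barcode = sprintf("%s_%s_%03d", sample_id,
                                         cell_class, idx))
  rd <- simulate_editing_reads(
    truth, site_c2t,
    edited_classes = tibble::tibble(sample_id = "S3",
                                    cell_class = "epithelial"),
    edit_rate = 0.5, coverage_mean = 5, error_rate = 0.001, seed = 53)
  calls <- call_site_editing(rd, site_c2t)
  summ <- summarize_editing(calls, truth)
  target <- summ$edited_fraction[summ$sample_id == "S3" &
                                   summ$cell_class == "epithelial"]
  others <- summ$edited_fraction[!(summ$sample_id == "S3" &
                                     summ$cell_class == "epithelial")]
  expect_true(all(target > others, na.rm = TRUE))
  expect_true(all(others <= 0.02, na.rm = TRUE))
})

test_that("reads_from_bam extracts base, barcode and UMI at the site", {
  skip_if_not_installed("Rsamtools")
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    # M-only read covering pos 100 (offset 3: base T, qual 'F' = 37)
    "r1\t0\tchr1\t98\t60\t8M\t*\t0\t0\tAATCGGCA\tFFFFFFFF\tCB:Z:CELL1\tUB:Z:U1",
    # read with a 2-base insertion before the site
    "r2\t0\tchr1\t95\t60\t3M2I5M\t*\t0\t0\tGGGTTCAACT\tFFFFFFFFFF\tCB:Z:CELL2\tUB:Z:U2",
    # site deleted in this read -> excluded
    "r3\t0\tchr1\t98\t60\t2M3D4M\t*\t0\t0\tAACGGT\tFFFFFF\tCB:Z:CELL3\tUB:Z:U3",
    # no CB tag -> excluded
    "r4\t0\tchr1\t99\t60\t4M\t*\t0\t0\tACGT\tFFFF\tUB:Z:U4")
  dir <- withr::local_tempdir()
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  bam <- Rsamtools::asBam(file.path(dir, "toy.sam"),
                          destination = file.path(dir, "toy"),
                          overwrite = TRUE, indexDestination = TRUE)
  rd <- reads_from_bam(bam, "chr1", 100, sample_id = "S1")
  expect_setequal(rd$read_id, c("r1", "r2"))
  r1 <- rd[rd$read_id == "r1", ]
  expect_equal(r1$base, "T")           # 98,99,100 -> A,A,T
  expect_equal(r1$base_quality, 37L)
  expect_equal(r1$cell_barcode, "CELL1")
  expect_equal(r1$umi, "U1")
  r2 <- rd[rd$read_id == "r2", ]
  # query: GGG (95-97) + TT insert + CAACT (98-102) -> pos 100 = offset 8 "A"
  expect_equal(r2$base, "A")
})
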