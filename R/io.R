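#' Read a 10x-convention Matrix Market directory
#'
#' Expects `matrix.mtx` (genes x cells triplets), `barcodes.tsv` (one
#' barcode per line) and `features.tsv` (columns gene_id, gene_symbol,
#' feature_type; extra columns ignored) in `dir`.
#'
#' @param dir Directory containing the three files.
#' @return A sparse genes x cells count matrix with dimnames.
#' @export
read_10x_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing file(s): ", paste(missing, collapse = ", ")))
  }
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  barcodes <- readLines(paths[2])
  features <- utils::read.delim(paths[3], header = FALSE,
                                stringsAsFactors = FALSE)
  if (length(barcodes) != ncol(m) || nrow(features) != nrow(m)) {
    abort("sidecar dimensions do not match the matrix")
  }
  dimnames(m) <- list(features[[1]], barcodes)
  m
}

#' Write a count matrix in the 10x Matrix Market convention
#'
#' Emits `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gene_id,
#' gene_symbol, feature_type) into `dir`, creating it if needed.
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param dir Output directory.
#' @param feature_type Feature type column value (default
#'   `"Gene Expression"`).
#' @return `dir`, invisibly.
#' @export
write_10x_mtx <- function(counts, dir, feature_type = "Gene Expression") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene and cell dimnames")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(rownames(counts), rownames(counts), feature_type),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a simulated dataset to disk
#'
#' Counts go out in the 10x Matrix Market convention; truth and annotation
#' as TSV.
#'
#' @param sim A [simulate_tumor_counts()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_mtx(sim$counts, file.path(dir, "counts"))
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(sim$clones)) {
    readr::write_tsv(sim$clones, file.path(dir, "clones.tsv"))
  }
  invisible(dir)
}

#' Read a read-level editing table from TSV
#'
#' Header must be exactly `read_id, umi, cell_barcode, sample_id, base,
#' base_quality`.
#'
#' @param path TSV path.
#' @return A read table tibble.
#' @export
read_reads_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           read_id = readr::col_character(),
                           umi = readr::col_character(),
                           cell_barcode = readr::col_character(),
                           sample_id = readr::col_character(),
                           base = readr::col_character(),
                           base_quality = readr::col_integer()))
  expected <- c("read_id", "umi", "cell_barcode", "sample_id", "base",
                "base_quality")
  if (!identical(names(out), expected)) {
    abort(paste0("read table header must be exactly: ",
                 paste(expected, collapse = ", ")))
  }
  out
}

#' Read a housekeeping gene list (one symbol per line)
#'
#' @param path Plain-text path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
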