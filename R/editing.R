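#' Describe a single-base RNA-editing site
#'
#' @param site_id Free-form site label, e.g. `"DDOST_558C>U"`.
#' @param ref_base,alt_base Reference and alternate base (`A/C/G/T`,
#'   distinct). C>U editing appears as C reference / T alternate in cDNA
#'   reads.
#' @param coordinate Optional free-form coordinate descriptor, carried
#'   through to outputs.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(site_id, ref_base, alt_base, coordinate = NA_character_) {
  bases <- c("A", "C", "G", "T")
  if (!ref_base %in% bases || !alt_base %in% bases) {
    abort("ref_base and alt_base must be one of A, C, G, T")
  }
  if (ref_base == alt_base) abort("ref_base and alt_base must differ")
  structure(list(site_id = site_id, ref_base = ref_base,
                 alt_base = alt_base, coordinate = coordinate),
            class = "site_spec")
}

#' Per-cell editing calls at a single site
#'
#' Reads below `min_base_quality` or with base `N` are discarded; the
#' survivors are collapsed per (cell, UMI) to the majority base (ties
#' discard the UMI). A cell with no surviving UMI is `unobserved`; a cell
#' with at least `min_alt_umis` alternate-base UMIs is `edited`; otherwise
#' `unedited`. Unobserved is never counted as unedited downstream.
#'
#' @param reads Read table with columns `read_id`, `umi`, `cell_barcode`,
#'   `sample_id`, `base`, `base_quality`.
#' @param site A [site_spec()].
#' @param min_base_quality Minimum Phred base quality (default 20).
#' @param min_alt_umis Alternate UMIs required to call `edited`
#'   (default 1).
#' @return A tibble, one row per cell appearing in `reads`:
#'   `cell_barcode`, `sample_id`, `n_reads`, `n_umis`, `n_alt_umis`,
#'   `call` (factor: `edited`, `unedited`, `unobserved`).
#' @export
call_site_editing <- function(reads, site, min_base_quality = 20L,
                              min_alt_umis = 1L) {
  stopifnot(inherits(site, "site_spec"))
  call_levels <- c("edited", "unedited", "unobserved")
  bad <- !reads$base %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    abort(paste0("invalid base for read(s): ",
                 paste(utils::head(reads$read_id[bad], 5), collapse = ", ")))
  }
  cells <- reads |>
    dplyr::distinct(.data$cell_barcode, .data$sample_id)
  n_reads_all <- reads |>
    dplyr::count(.data$cell_barcode, name = "n_reads")
  kept <- reads[reads$base_quality >= min_base_quality & reads$base != "N", ]
  if (nrow(kept) > 0) {
    umi_calls <- kept |>
      dplyr::count(.data$cell_barcode, .data$umi, .data$base) |>
      dplyr::group_by(.data$cell_barcode, .data$umi) |>
      dplyr::filter(.data$n == max(.data$n)) |>
      dplyr::filter(dplyr::n() == 1) |>   # ties discard the UMI
      dplyr::ungroup()
    per_cell <- umi_calls |>
      dplyr::group_by(.data$cell_barcode) |>
      dplyr::summarise(n_umis = dplyr::n(),
                       n_alt_umis = sum(.data$base == site$alt_base))
  } else {
    per_cell <- tibble(cell_barcode = character(), n_umis = integer(),
                       n_alt_umis = integer())
  }
  out <- cells |>
    dplyr::left_join(n_reads_all, by = "cell_barcode") |>
    dplyr::left_join(per_cell, by = "cell_barcode") |>
    dplyr::mutate(
      n_umis = dplyr::coalesce(.data$n_umis, 0L),
      n_alt_umis = dplyr::coalesce(.data$n_alt_umis, 0L),
      call = factor(dplyr::case_when(
        .data$n_umis == 0 ~ "unobserved",
        .data$n_alt_umis >= min_alt_umis ~ "edited",
        TRUE ~ "unedited"
      ), levels = call_levels)
    ) |>
    dplyr::arrange(.data$cell_barcode)
  attr(out, "site") <- site
  out
}

#' Stratified editing summary
#'
#' Counts covered and edited cells per (sample, cell class) stratum.
#' Denominators use covered cells only: `edited_fraction =
#' n_cells_edited / n_cells_covered`, `NA` when no cell is covered.
#' Optionally collapses classes into a binary epithelial / non-epithelial
#' grouping.
#'
#' @param calls Per-cell calls from [call_site_editing()].
#' @param cell_metadata Tibble with `cell_barcode`, `sample_id`,
#'   `cell_class` covering all called cells; cells in the metadata without
#'   reads count as unobserved.
#' @param class_collapse Optional named character vector mapping each
#'   class to a collapsed label (e.g. `c(epithelial = "Epi", T_cell =
#'   "non-Epi", ...)`).
#' @return A tibble per (sample_id, cell_class): `n_cells_total`,
#'   `n_cells_covered`, `n_cells_edited`, `edited_fraction`.
#' @export
summarize_editing <- function(calls, cell_metadata, class_collapse = NULL) {
  missing <- setdiff(calls$cell_barcode, cell_metadata$cell_barcode)
  if (length(missing) > 0) {
    abort(paste0("cells without metadata: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  meta <- cell_metadata[, c("cell_barcode", "sample_id", "cell_class")]
  if (!is.null(class_collapse)) {
    unmapped <- setdiff(unique(meta$cell_class), names(class_collapse))
    if (length(unmapped) > 0) {
      abort(paste0("class_collapse does not map class(es): ",
                   paste(unmapped, collapse = ", ")))
    }
    meta$cell_class <- unname(class_collapse[meta$cell_class])
  }
  joined <- meta |>
    dplyr::left_join(calls[, c("cell_barcode", "call")], by = "cell_barcode") |>
    dplyr::mutate(call = forcats_replace_na(.data$call))
  joined |>
    dplyr::group_by(.data$sample_id, .data$cell_class) |>
    dplyr::summarise(
      n_cells_total = dplyr::n(),
      n_cells_covered = sum(.data$call != "unobserved"),
      n_cells_edited = sum(.data$call == "edited"),
      .groups = "drop"
    ) |>
    dplyr::mutate(edited_fraction = ifelse(
      .data$n_cells_covered > 0,
      .data$n_cells_edited / .data$n_cells_covered, NA_real_))
}

# NA call (cell absent from the read table) means unobserved
forcats_replace_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "unobserved"
  factor(x, levels = c("edited", "unedited", "unobserved"))
}

#' Extract site reads from a coordinate-sorted BAM/SAM alignment
#'
#' Optional adapter producing the read table consumed by
#' [call_site_editing()] from a 10x-style alignment: reads overlapping a
#' 1-based genomic position are scanned, the base and base quality at the
#' position are extracted (CIGAR-aware), and cell barcode / UMI are taken
#' from the `CB` / `UB` tags. Requires the `Rsamtools` package.
#'
#' @param bam_path Path to an indexed BAM file.
#' @param chrom,pos Reference name and 1-based position of the site.
#' @param sample_id Sample label attached to every read.
#' @param cb_tag,umi_tag Barcode and UMI tag names (default `CB`, `UB`).
#' @return A read table tibble as described in [call_site_editing()].
#' @export
reads_from_bam <- function(bam_path, chrom, pos, sample_id = "sample",
                           cb_tag = "CB", umi_tag = "UB") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reads_from_bam requires the Rsamtools package")
  }
  which <- GenomicRanges_range(chrom, pos)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar", "seq", "qual"),
    tag = c(cb_tag, umi_tag), which = which)
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$qname)
  empty <- tibble(read_id = character(), umi = character(),
                  cell_barcode = character(), sample_id = character(),
                  base = character(), base_quality = integer())
  if (n == 0) return(empty)
  cb <- res$tag[[cb_tag]] %||% rep(NA_character_, n)
  ub <- res$tag[[umi_tag]] %||% rep(NA_character_, n)
  rows <- lapply(seq_len(n), function(i) {
    off <- query_offset_at(res$cigar[i], res$pos[i], pos)
    if (is.na(off)) return(NULL)
    if (is.na(cb[i]) || is.na(ub[i])) return(NULL)
    tibble(read_id = res$qname[i], umi = ub[i], cell_barcode = cb[i],
           sample_id = sample_id,
           base = toupper(substr(as.character(res$seq[i]), off, off)),
           base_quality = as.integer(
             utf8ToInt(substr(as.character(res$qual[i]), off, off)) - 33L))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

GenomicRanges_range <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
}

# 1-based offset into the query sequence of reference position `target`,
# walking the CIGAR; NA when the position is deleted/skipped or outside.
query_offset_at <- function(cigar, aln_start, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ref <- aln_start; q <- 1L
  for (op in ops) {
    len <- as.integer(sub("[MIDNSHP=X]", "", op))
    code <- sub("\\d+", "", op)
    if (code %in% c("M", "=", "X")) {
      if (target >= ref && target < ref + len) return(q + (target - ref))
      ref <- ref + len; q <- q + len
    } else if (code %in% c("I", "S")) {
      q <- q + len
    } else if (code %in% c("D", "N")) {
      if (target >= ref && target < ref + len) return(NA_integer_)
      ref <- ref + len
    }
  }
  NA_integer_
}
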