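#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect: one set per line, fields
#' `name`, `description`, then one gene symbol per field. Duplicate genes
#' within a line are deduplicated; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble of class `gene_set_collection` with columns
#'   `set_name`, `description`, `genes` (list column of character
#'   vectors), `set_size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate gene-set name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  out <- tibble(
    set_name = nm,
    description = vapply(fields, `[[`, character(1), 2),
    genes = genes,
    set_size = lengths(genes)
  )
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors.
#' @param description Optional descriptions (recycled).
#' @return A `gene_set_collection` tibble as from [read_gmt()].
#' @export
gene_set_collection <- function(sets, description = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("sets must be a uniquely named list")
  }
  genes <- lapply(sets, unique)
  out <- tibble(set_name = names(sets),
                description = rep_len(description, length(sets)),
                genes = unname(genes), set_size = lengths(genes))
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each set `S`, tests whether the differentially expressed gene list
#' overlaps `S` more than expected by chance, with the upper-tail
#' hypergeometric probability `P(X >= k)` for `k = |S n DE|` successes in
#' `n = |DE|` draws from a universe of `M` genes containing
#' `K = |S n universe|` set members. Q-values are Benjamini-Hochberg over
#' all sets represented in the universe (`K > 0`).
#'
#' @param de_genes Character vector of selected genes (e.g. from
#'   [de_genes()]). Genes outside the universe are dropped with a warning.
#' @param universe Character vector: all genes tested for DE.
#' @param sets A `gene_set_collection` ([read_gmt()] or
#'   [gene_set_collection()]).
#' @return A tibble ordered by `p_value`: `set_name`, `overlap_k`,
#'   `set_size_K`, `de_size_n`, `universe_size_M`, `p_value`, `q_value`,
#'   `overlap_genes` (list column).
#' @export
ora_enrichment <- function(de_genes, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe is empty")
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " DE gene(s) outside the universe dropped"))
    de_genes <- intersect(de_genes, universe)
  }
  m_univ <- length(universe)
  n_de <- length(de_genes)
  res <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    in_univ <- intersect(sets$genes[[i]], universe)
    k_set <- length(in_univ)
    overlap <- intersect(in_univ, de_genes)
    k <- length(overlap)
    p <- if (k_set == 0) NA_real_ else {
      stats::phyper(k - 1, k_set, m_univ - k_set, n_de, lower.tail = FALSE)
    }
    tibble(set_name = sets$set_name[i], overlap_k = k, set_size_K = k_set,
           de_size_n = n_de, universe_size_M = m_univ, p_value = p,
           overlap_genes = list(overlap))
  })
  res$q_value <- NA_real_
  idx <- !is.na(res$p_value)
  res$q_value[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  res <- res[order(res$p_value, res$set_name),
             c("set_name", "overlap_k", "set_size_K", "de_size_n",
               "universe_size_M", "p_value", "q_value", "overlap_genes")]
  res
}

#' Over-representation analysis straight from a DE table
#'
#' Thresholds the table with [de_genes()] (absolute linear fold change and
#' adjusted p), uses all tested genes as the universe, and runs
#' [ora_enrichment()].
#'
#' @inheritParams de_genes
#' @inheritParams ora_enrichment
#' @return See [ora_enrichment()].
#' @export
ora_from_de <- function(de_table, sets, fc_threshold = 1.8,
                        padj_threshold = 0.05) {
  ora_enrichment(de_genes(de_table, fc_threshold, padj_threshold),
                 universe = de_table$gene_id, sets = sets)
}
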