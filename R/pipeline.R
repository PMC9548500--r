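#' Assemble a pipeline configuration
#'
#' Collects everything the end-to-end run needs: either a simulation block
#' or paths to on-disk inputs, per-stage parameters, a seed and an output
#' directory. Validation happens in [run_pipeline()] before any compute,
#' reporting all schema violations at once.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in every stage's provenance.
#' @param simulate `NULL`, or a list describing a [simulate_tumor_counts()]
#'   run: `genome` (args for [make_genome()]), `clones`, `plans`, and
#'   optionally `editing` (args for [simulate_editing_reads()]:
#'   `edited_classes`, `edit_rate`, `coverage_mean`, `error_rate`).
#' @param inputs `NULL`, or a list of paths: `matrix_dir` (10x MTX
#'   directory), `annotation` (TSV), `metadata` (TSV: `cell_barcode`,
#'   `sample_id`, `cell_class`), optionally `reads` (TSV read table).
#' @param qc A [qc_thresholds()] object.
#' @param cna List: `params` ([cna_params()]), `reference_classes`,
#'   `malignant_classes`.
#' @param clonality `NULL`, or list: `tested_pairs` (two-column tibble of
#'   sample labels), optional `related_pairs`, `method`.
#' @param de `NULL`, or list: `cell_class`, `samples_a`, `samples_b`,
#'   optional `min_pct`, `fc_threshold`, `padj_threshold`.
#' @param ora `NULL`, or list: `gmt` (path) or `sets`
#'   (a [gene_set_collection()]).
#' @param editing `NULL`, or list: `site` ([site_spec()]), optional
#'   `min_base_quality`, `min_alt_umis`, `class_collapse`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            inputs = NULL, qc = qc_thresholds(),
                            cna = list(params = cna_params(),
                                       reference_classes = c("T_cell", "B_cell"),
                                       malignant_classes = "epithelial"),
                            clonality = NULL, de = NULL, ora = NULL,
                            editing = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, qc = qc, cna = cna,
                 clonality = clonality, de = de, ora = ora,
                 editing = editing),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema check run before any compute; every violation is collected and
#' reported in one error.
#'
#' @param config A [pipeline_config()].
#' @return `config`, invisibly, when valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  if (!inherits(config, "pipeline_config")) add("not a pipeline_config")
  if (is.null(config$out_dir)) add("out_dir: missing")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    add("one of 'simulate' or 'inputs' is required")
  }
  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    add("'simulate' and 'inputs' are mutually exclusive")
  }
  if (!is.null(config$simulate)) {
    for (f in c("genome", "plans")) {
      if (is.null(config$simulate[[f]])) add(paste0("simulate$", f, ": missing"))
    }
  }
  if (!is.null(config$inputs)) {
    for (f in c("matrix_dir", "annotation", "metadata")) {
      p <- config$inputs[[f]]
      if (is.null(p)) add(paste0("inputs$", f, ": missing"))
      else if (!file.exists(p)) add(paste0("inputs$", f, ": path does not exist: ", p))
    }
  }
  if (!inherits(config$qc, "qc_thresholds")) add("qc: must be qc_thresholds()")
  if (is.null(config$cna$params) || !inherits(config$cna$params, "cna_params")) {
    add("cna$params: must be cna_params()")
  }
  if (is.null(config$cna$reference_classes)) add("cna$reference_classes: missing")
  if (!is.null(config$clonality) && is.null(config$clonality$tested_pairs)) {
    add("clonality$tested_pairs: missing")
  }
  if (!is.null(config$de)) {
    for (f in c("cell_class", "samples_a", "samples_b")) {
      if (is.null(config$de[[f]])) add(paste0("de$", f, ": missing"))
    }
  }
  if (!is.null(config$ora)) {
    if (is.null(config$ora$gmt) && is.null(config$ora$sets)) {
      add("ora$gmt: missing (no GMT path or sets given with ORA enabled)")
    } else if (!is.null(config$ora$gmt) && !file.exists(config$ora$gmt)) {
      add(paste0("ora$gmt: path does not exist: ", config$ora$gmt))
    }
    if (is.null(config$de)) add("ora requires a de block")
  }
  if (!is.null(config$editing) &&
      !inherits(config$editing$site, "site_spec")) {
    add("editing$site: must be site_spec()")
  }
  if (length(errs) > 0) {
    abort(paste0("invalid pipeline config:\n",
                 paste0("  - ", errs, collapse = "\n")))
  }
  invisible(config)
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  tibble(file = basename(names(sums)), md5 = unname(sums))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load inputs), QC, CNA inference,
#' clonality testing, differential expression, over-representation, and
#' editing detection — skipping stages whose configuration block is
#' `NULL`. Each stage writes its TSV/MTX outputs under `out_dir` and is
#' recorded in a machine-readable run report (stage, counts in/out, output
#' files with MD5 checksums, seed). A failing stage halts the run with an
#' error naming the stage.
#'
#' @param config A [pipeline_config()]; validated before any compute.
#' @return A tibble run report (one row per executed stage), invisibly
#'   also written to `out_dir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  note <- function(stage, n_in, n_out, files) {
    report[[stage]] <<- tibble(
      stage = stage, status = "ok", n_in = n_in, n_out = n_out,
      files = list(checksum_files(files)), seed = config$seed)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # --- stage 1: simulate or load --------------------------------------
  if (!is.null(config$simulate)) {
    run_stage("simulate", {
      sim_cfg <- config$simulate
      annotation <- do.call(make_genome,
                            c(sim_cfg$genome, list(seed = config$seed)))
      sim <- simulate_tumor_counts(
        annotation, sim_cfg$clones, sim_cfg$plans,
        baseline_mean_shape = sim_cfg$baseline_mean_shape %||% 0.5,
        dispersion = sim_cfg$dispersion %||% 0.3,
        mito_share = sim_cfg$mito_share %||% 0.05,
        hk_boost = sim_cfg$hk_boost %||% 30,
        marker_genes_per_class = sim_cfg$marker_genes_per_class %||% 0L,
        marker_boost = sim_cfg$marker_boost %||% 5,
        seed = config$seed + 1L)
      sim_dir <- file.path(config$out_dir, "simulated")
      write_sim_dataset(sim, sim_dir)
      counts <- sim$counts
      metadata <- sim$truth[, c("cell_barcode", "sample_id", "cell_class")]
      reads <- NULL
      if (!is.null(sim_cfg$editing) && !is.null(config$editing)) {
        reads <- simulate_editing_reads(
          sim$truth[!sim$truth$is_doublet, ], config$editing$site,
          edited_classes = sim_cfg$editing$edited_classes,
          edit_rate = sim_cfg$editing$edit_rate %||% 0.5,
          coverage_mean = sim_cfg$editing$coverage_mean %||% 5,
          error_rate = sim_cfg$editing$error_rate %||% 0.001,
          seed = config$seed + 2L)
        readr::write_tsv(reads, file.path(sim_dir, "editing_reads.tsv"))
      }
      note("simulate", nrow(sim$truth), ncol(counts),
           file.path(sim_dir, c("counts/matrix.mtx", "counts/barcodes.tsv",
                                "counts/features.tsv", "annotation.tsv",
                                "truth.tsv", "editing_reads.tsv")))
    })
  } else {
    run_stage("load", {
      counts <- read_10x_mtx(config$inputs$matrix_dir)
      annotation <- readr::read_tsv(config$inputs$annotation,
                                    show_col_types = FALSE)
      metadata <- readr::read_tsv(config$inputs$metadata,
                                  show_col_types = FALSE)
      reads <- if (!is.null(config$inputs$reads)) {
        read_reads_tsv(config$inputs$reads)
      }
      note("load", ncol(counts), ncol(counts), character())
    })
  }

  # --- stage 2: QC ----------------------------------------------------
  run_stage("qc", {
    norm <- lognormalize(counts)
    ds <- doublet_scores(counts, seed = config$seed + 3L)
    qc_tab <- cell_qc_metrics(counts, annotation, norm, doublet_score = ds)
    filt <- apply_qc(counts, qc_tab, config$qc)
    readr::write_tsv(qc_tab, file.path(config$out_dir, "qc_metrics.tsv"))
    readr::write_tsv(filt$report, file.path(config$out_dir, "qc_report.tsv"))
    write_10x_mtx(filt$counts, file.path(config$out_dir, "filtered_counts"))
    counts <- filt$counts
    metadata <- metadata[metadata$cell_barcode %in% colnames(counts), ]
    norm <- lognormalize(counts)
    note("qc", nrow(qc_tab), ncol(counts),
         file.path(config$out_dir,
                   c("qc_metrics.tsv", "qc_report.tsv",
                     "filtered_counts/matrix.mtx")))
  })

  # --- stage 3: CNA inference ----------------------------------------
  cna <- NULL
  if (!is.null(config$cna$reference_classes)) {
    run_stage("cna", {
      ref_cells <- metadata$cell_barcode[
        metadata$cell_class %in% config$cna$reference_classes]
      query_cells <- setdiff(metadata$cell_barcode, ref_cells)
      cna <- infer_cna_matrix(norm, annotation, ref_cells, query_cells,
                              config$cna$params)
      out <- dplyr::bind_cols(cna$genes, as_tibble(cna$cna))
      readr::write_tsv(out, file.path(config$out_dir, "cna_matrix.tsv"))
      note("cna", ncol(norm), ncol(cna$cna),
           file.path(config$out_dir, "cna_matrix.tsv"))
    })
  }

  # --- stage 4: clonality --------------------------------------------
  if (!is.null(config$clonality) && !is.null(cna)) {
    run_stage("clonality", {
      mal <- metadata[metadata$cell_class %in%
                        (config$cna$malignant_classes %||% "epithelial"), ]
      groups <- tibble(cell_barcode = mal$cell_barcode, group = mal$sample_id)
      profiles <- mean_cna_profiles(cna, groups)
      res <- test_clonality(profiles, config$clonality$tested_pairs,
                            related_pairs = config$clonality$related_pairs,
                            method = config$clonality$method %||% "gaussian")
      readr::write_tsv(tidy(res), file.path(config$out_dir, "clonality_pvalues.tsv"))
      readr::write_tsv(as_tibble(res$r_matrix, rownames = "group"),
                       file.path(config$out_dir, "clonality_r_matrix.tsv"))
      readr::write_tsv(tibble(pair = names(res$null_sample),
                              r = unname(res$null_sample)),
                       file.path(config$out_dir, "clonality_null.tsv"))
      note("clonality", ncol(profiles$profiles), nrow(tidy(res)),
           file.path(config$out_dir,
                     c("clonality_pvalues.tsv", "clonality_r_matrix.tsv",
                       "clonality_null.tsv")))
    })
  }

  # --- stage 5: differential expression ------------------------------
  de_tab <- NULL
  if (!is.null(config$de)) {
    run_stage("de", {
      in_class <- metadata[metadata$cell_class %in% config$de$cell_class, ]
      cells_a <- in_class$cell_barcode[
        in_class$sample_id %in% config$de$samples_a]
      cells_b <- in_class$cell_barcode[
        in_class$sample_id %in% config$de$samples_b]
      de_tab <- wilcoxon_de(norm, cells_a, cells_b,
                            min_pct = config$de$min_pct %||% 0.1)
      readr::write_tsv(de_tab, file.path(config$out_dir, "de_table.tsv"))
      note("de", length(cells_a) + length(cells_b), nrow(de_tab),
           file.path(config$out_dir, "de_table.tsv"))
    })
  }

  # --- stage 6: over-representation ----------------------------------
  if (!is.null(config$ora) && !is.null(de_tab)) {
    run_stage("ora", {
      sets <- config$ora$sets %||% read_gmt(config$ora$gmt)
      enr <- ora_from_de(de_tab, sets,
                         fc_threshold = config$de$fc_threshold %||% 1.8,
                         padj_threshold = config$de$padj_threshold %||% 0.05)
      out <- enr
      out$overlap_genes <- vapply(out$overlap_genes, paste, character(1),
                                  collapse = ",")
      readr::write_tsv(out, file.path(config$out_dir, "ora_table.tsv"))
      note("ora", nrow(sets), nrow(enr),
           file.path(config$out_dir, "ora_table.tsv"))
    })
  }

  # --- stage 7: editing ----------------------------------------------
  if (!is.null(config$editing) && !is.null(reads) && nrow(reads) > 0) {
    run_stage("editing", {
      calls <- call_site_editing(
        reads, config$editing$site,
        min_base_quality = config$editing$min_base_quality %||% 20L,
        min_alt_umis = config$editing$min_alt_umis %||% 1L)
      # QC-dropped cells carry no metadata; restrict calls to kept cells
      meta_ed <- metadata
      if (!is.null(config$editing$class_collapse)) {
        meta_ed <- meta_ed[meta_ed$cell_class %in%
                             names(config$editing$class_collapse), ]
      }
      calls <- calls[calls$cell_barcode %in% meta_ed$cell_barcode, ]
      summ <- summarize_editing(calls, cell_metadata = meta_ed,
                                class_collapse = config$editing$class_collapse)
      readr::write_tsv(calls, file.path(config$out_dir, "editing_calls.tsv"))
      readr::write_tsv(summ, file.path(config$out_dir, "editing_summary.tsv"))
      note("editing", nrow(reads), nrow(calls),
           file.path(config$out_dir,
                     c("editing_calls.tsv", "editing_summary.tsv")))
    })
  }

  report <- dplyr::bind_rows(report)
  json <- lapply(seq_len(nrow(report)), function(i) {
    list(stage = report$stage[i], status = report$status[i],
         n_in = report$n_in[i], n_out = report$n_out[i],
         seed = report$seed[i],
         files = report$files[[i]])
  })
  jsonlite::write_json(json, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' A small bundled example configuration
#'
#' Five tumor samples (~1,100 cells total, 6 autosomes x 80 genes); two
#' samples share a malignant clone (the pair under test), the other three
#' carry distinct private clones and provide the unrelated-pair null. An
#' editing site is active in one sample's epithelial cells, and a toy
#' gene-set collection feeds the over-representation stage — small enough
#' for an end-to-end run in seconds.
#'
#' @param out_dir Output directory for the run.
#' @param seed Integer seed.
#' @return A validated [pipeline_config()].
#' @export
example_pipeline_config <- function(out_dir, seed = 1L) {
  clones <- tibble(
    clone_id = c("shared", "shared", "privA", "privB", "privC"),
    chromosome = c("1", "3", "5", "2", "4"),
    start = c(1L, 1L, 1L, 1L, 1L),
    end = c(800000L, 500000L, 800000L, 600000L, 700000L),
    multiplier = c(2.0, 0.5, 1.8, 0.5, 2.0)
  )
  mk <- function(s, clone, dbl = 0.03) {
    cell_plan(s, c("epithelial", "T_cell", "B_cell"), c(120, 60, 40),
              clone_id = c(clone, NA, NA), doublet_fraction = dbl)
  }
  plans <- dplyr::bind_rows(
    mk("T1", "shared"), mk("T2", "shared"), mk("T3", "privA"),
    mk("T4", "privB"), mk("T5", "privC")
  )
  genome <- list(n_chromosomes = 6, genes_per_chromosome = 80,
                 n_mito = 10, n_housekeeping = 30)
  sets <- gene_set_collection(list(
    SET_CHR5_START = sprintf("gene_5_%04d", 1:40),
    SET_CHR2 = sprintf("gene_2_%04d", 1:40),
    SET_MIXED = c(sprintf("gene_6_%04d", 1:20), sprintf("gene_4_%04d", 1:20))
  ), description = "toy sets")
  pipeline_config(
    out_dir = out_dir, seed = seed,
    simulate = list(
      genome = genome, clones = clones, plans = plans,
      marker_genes_per_class = 40L, marker_boost = 6,
      editing = list(
        edited_classes = tibble(sample_id = "T3", cell_class = "epithelial"),
        edit_rate = 0.5, coverage_mean = 5, error_rate = 0.001)),
    qc = qc_thresholds(min_genes = 50, max_genes = 100000, min_umi = 200,
                       doublet_threshold = 0.75),
    cna = list(params = cna_params(window = 51),
               reference_classes = c("T_cell", "B_cell"),
               malignant_classes = "epithelial"),
    clonality = list(tested_pairs = tibble(a = "T1", b = "T2")),
    de = list(cell_class = "epithelial", samples_a = "T3",
              samples_b = c("T1", "T2"), fc_threshold = 1.5),
    ora = list(sets = sets),
    editing = list(site = site_spec("DDOST_558C>U", "C", "T",
                                    coordinate = "chr1:20981977"),
                   class_collapse = c(epithelial = "Epi", T_cell = "non-Epi",
                                      B_cell = "non-Epi"))
  )
}
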