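#' Generate a synthetic genome annotation
#'
#' Builds a gene annotation table with evenly spaced genes on numerically
#' labelled autosomes, a mitochondrial contig `"MT"`, and a random subset of
#' autosomal genes flagged as housekeeping. Housekeeping genes receive
#' inflated expression baselines in [simulate_tumor_counts()], so the
#' housekeeping QC criterion has a well-defined ground truth.
#'
#' @param n_chromosomes Number of autosomes (labelled `"1"`, `"2"`, ...).
#' @param genes_per_chromosome Genes placed on each autosome.
#' @param n_mito Number of mitochondrial genes (chromosome `"MT"`).
#' @param n_housekeeping Number of autosomal genes flagged `housekeeping`.
#' @param seed Integer seed; fixes the housekeeping assignment.
#'
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `category` (one of `ordinary`, `mitochondrial`, `housekeeping`).
#'   Within each chromosome starts are strictly increasing.
#' @export
make_genome <- function(n_chromosomes, genes_per_chromosome,
                        n_mito = 0, n_housekeeping = 0, seed = 1L) {
  if (n_chromosomes < 1 || genes_per_chromosome < 1) {
    abort("n_chromosomes and genes_per_chromosome must be positive")
  }
  if (n_mito < 0 || n_housekeeping < 0) {
    abort("n_mito and n_housekeeping must be non-negative")
  }
  n_auto <- n_chromosomes * genes_per_chromosome
  if (n_housekeeping > n_auto) {
    abort("n_housekeeping cannot exceed the number of autosomal genes")
  }
  gene_span <- 1000L
  gene_gap <- 10000L
  auto <- tibble(
    chromosome = rep(as.character(seq_len(n_chromosomes)),
                     each = genes_per_chromosome),
    idx = rep(seq_len(genes_per_chromosome), times = n_chromosomes)
  )
  auto$gene_id <- sprintf("gene_%s_%04d", auto$chromosome, auto$idx)
  auto$start <- (auto$idx - 1L) * gene_gap + 1L
  auto$end <- auto$start + gene_span - 1L
  auto$category <- "ordinary"
  with_seed(seed, {
    if (n_housekeeping > 0) {
      hk <- sample.int(n_auto, n_housekeeping)
      auto$category[hk] <- "housekeeping"
    }
  })
  out <- auto[, c("gene_id", "chromosome", "start", "end", "category")]
  if (n_mito > 0) {
    mito <- tibble(
      gene_id = sprintf("gene_MT_%04d", seq_len(n_mito)),
      chromosome = "MT",
      start = (seq_len(n_mito) - 1L) * gene_gap + 1L,
      end = (seq_len(n_mito) - 1L) * gene_gap + gene_span,
      category = "mitochondrial"
    )
    out <- dplyr::bind_rows(out, mito)
  }
  out
}

#' Describe the cells to simulate for one or more samples
#'
#' Convenience constructor for the cell plan consumed by
#' [simulate_tumor_counts()]. One row per (sample, cell class); malignant
#' classes reference a clone, reference classes leave `clone_id` `NA`.
#' Library sizes are log-normal per cell with the given per-sample
#' parameters, and `doublet_fraction` of each sample's planned cells are
#' appended as heterotypic doublets.
#'
#' @param sample_id,cell_class,n_cells Vectors, recycled to common length.
#' @param clone_id Clone label per row (`NA` for reference classes).
#' @param doublet_fraction Fraction in `[0, 1)` of the sample's planned
#'   cells appended as doublets.
#' @param lib_size_meanlog,lib_size_sdlog Log-normal library-size model.
#' @return A tibble usable as the `plans` argument of
#'   [simulate_tumor_counts()].
#' @export
cell_plan <- function(sample_id, cell_class, n_cells, clone_id = NA_character_,
                      doublet_fraction = 0, lib_size_meanlog = log(10000),
                      lib_size_sdlog = 0.3) {
  tibble(
    sample_id = sample_id, cell_class = cell_class,
    n_cells = as.integer(n_cells), clone_id = as.character(clone_id),
    doublet_fraction = doublet_fraction,
    lib_size_meanlog = lib_size_meanlog, lib_size_sdlog = lib_size_sdlog
  )
}

# Per-gene copy multipliers for one clone: a gene belongs to a segment when
# its start coordinate falls inside [start, end]; genes outside any segment
# are copy-neutral (1.0).
clone_multipliers <- function(annotation, clones, clone) {
  mult <- rep(1, nrow(annotation))
  if (is.null(clones) || is.na(clone)) return(mult)
  segs <- clones[clones$clone_id == clone, , drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    if (!segs$chromosome[i] %in% annotation$chromosome) {
      abort(sprintf(
        "clone '%s' segment %s:%d-%d references unknown chromosome '%s'",
        clone, segs$chromosome[i], segs$start[i], segs$end[i],
        segs$chromosome[i]))
    }
    hit <- annotation$chromosome == segs$chromosome[i] &
      annotation$start >= segs$start[i] & annotation$start <= segs$end[i]
    mult[hit] <- mult[hit] * segs$multiplier[i]
  }
  mult
}

validate_clones <- function(clones, annotation) {
  if (is.null(clones) || nrow(clones) == 0) return(invisible(NULL))
  needed <- c("clone_id", "chromosome", "start", "end", "multiplier")
  missing <- setdiff(needed, names(clones))
  if (length(missing) > 0) {
    abort(paste0("clones is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(clones$multiplier <= 0)) abort("copy multipliers must be positive")
  bad <- !clones$chromosome %in% annotation$chromosome
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "clone '%s' segment %s:%d-%d references unknown chromosome '%s'",
      clones$clone_id[i], clones$chromosome[i], clones$start[i],
      clones$end[i], clones$chromosome[i]))
  }
  # non-overlap within (clone, chromosome)
  split_key <- paste(clones$clone_id, clones$chromosome)
  for (grp in split(seq_len(nrow(clones)), split_key)) {
    if (length(grp) < 2) next
    segs <- clones[grp, ][order(clones$start[grp]), ]
    if (any(segs$start[-1] <= segs$end[-nrow(segs)])) {
      abort(sprintf("overlapping segments for clone '%s' on chromosome %s",
                    segs$clone_id[1], segs$chromosome[1]))
    }
  }
  invisible(NULL)
}

#' Simulate multi-tumor scRNA-seq counts with known clone CNA structure
#'
#' Draws per-gene baseline means once from a gamma distribution (shared by
#' all samples), multiplies them by each clone's segment copy multipliers
#' and a per-cell log-normal library-size factor, and samples observed UMI
#' counts from a negative binomial with a single global dispersion.
#' Housekeeping genes get a `hk_boost`-fold inflated baseline so typical
#' singlets clear the housekeeping QC threshold; mitochondrial genes are
#' scaled to take an expected `mito_share` of each cell's counts. Doublets
#' are formed by summing the counts of two independently drawn parent
#' cells (classes sampled uniformly) and flagged in the truth table.
#'
#' @param annotation Gene annotation from [make_genome()] (or equivalent).
#' @param clones Tibble of segments: `clone_id`, `chromosome`, `start`,
#'   `end`, `multiplier` (1.0 = copy-neutral). `NULL` for no CNAs.
#' @param plans Cell plan from [cell_plan()].
#' @param baseline_mean_shape Gamma shape of per-gene baseline means.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param mito_share Expected fraction of each cell's counts coming from
#'   mitochondrial genes.
#' @param hk_boost Baseline multiplier for housekeeping genes.
#' @param marker_genes_per_class Number of ordinary genes boosted as a
#'   class-specific expression program (default 0: all classes share one
#'   baseline and are exchangeable when no clone segments exist). Set
#'   positive to make cell classes well-separated in expression space,
#'   e.g. for doublet-detection studies.
#' @param marker_boost Baseline multiplier at a class's marker genes.
#' @param seed Integer seed; fixes every emitted byte.
#'
#' @return An object of class `sim_dataset`: a list with `counts` (sparse
#'   genes x cells integer matrix), `annotation`, `truth` (one row per
#'   cell: `cell_barcode`, `sample_id`, `cell_class`, `clone_id`,
#'   `is_doublet`, parent classes for doublets), `clones` and `params`.
#' @export
simulate_tumor_counts <- function(annotation, clones, plans,
                                  baseline_mean_shape = 0.5,
                                  dispersion = 0.3,
                                  mito_share = 0.05,
                                  hk_boost = 30,
                                  marker_genes_per_class = 0L,
                                  marker_boost = 5,
                                  seed = 1L) {
  check_annotation(annotation)
  if (!"category" %in% names(annotation)) annotation$category <- "ordinary"
  validate_clones(clones, annotation)
  if (baseline_mean_shape <= 0 || dispersion <= 0) {
    abort("baseline_mean_shape and dispersion must be positive")
  }
  planned_clones <- unique(stats::na.omit(plans$clone_id))
  known_clones <- if (is.null(clones)) character() else unique(clones$clone_id)
  unknown <- setdiff(planned_clones, known_clones)
  if (length(unknown) > 0) {
    abort(paste0("plan references unknown clone(s): ",
                 paste(unknown, collapse = ", ")))
  }

  n_genes <- nrow(annotation)
  is_mito <- annotation$category == "mitochondrial"
  is_hk <- annotation$category == "housekeeping"

  with_seed(seed, {
    baseline <- stats::rgamma(n_genes, shape = baseline_mean_shape,
                              rate = baseline_mean_shape)
    baseline <- pmax(baseline, 1e-4)
    baseline[is_hk] <- baseline[is_hk] * hk_boost
    if (any(is_mito)) {
      non_mito_total <- sum(baseline[!is_mito])
      target <- mito_share / (1 - mito_share) * non_mito_total
      baseline[is_mito] <- baseline[is_mito] / sum(baseline[is_mito]) * target
    }

    size <- 1 / dispersion
    mult_cache <- lapply(stats::setNames(planned_clones, planned_clones),
                         function(cl) clone_multipliers(annotation, clones, cl))

    # optional class-specific expression programs (disjoint marker panels)
    all_classes <- sort(unique(plans$cell_class))
    class_mult <- lapply(stats::setNames(all_classes, all_classes),
                         function(cl) rep(1, n_genes))
    if (marker_genes_per_class > 0) {
      ordinary <- which(annotation$category == "ordinary")
      need <- marker_genes_per_class * length(all_classes)
      if (need > length(ordinary)) {
        abort("not enough ordinary genes for the requested marker panels")
      }
      pool <- sample(ordinary, need)
      for (i in seq_along(all_classes)) {
        idx <- pool[seq.int((i - 1) * marker_genes_per_class + 1,
                            i * marker_genes_per_class)]
        class_mult[[all_classes[i]]][idx] <- marker_boost
      }
    }

    draw_cells <- function(n, clone, cls, meanlog, sdlog) {
      mult <- if (is.na(clone)) rep(1, n_genes) else mult_cache[[clone]]
      mu_gene <- baseline * mult * class_mult[[cls]]
      lib <- stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
      scale <- lib / sum(mu_gene)
      mu <- mu_gene %o% scale
      matrix(stats::rnbinom(n_genes * n, size = size, mu = mu),
             nrow = n_genes)
    }

    blocks <- list()
    truth <- list()
    for (s in unique(plans$sample_id)) {
      sp <- plans[plans$sample_id == s, , drop = FALSE]
      cls_mat <- vector("list", nrow(sp))
      for (i in seq_len(nrow(sp))) {
        cls_mat[[i]] <- draw_cells(sp$n_cells[i], sp$clone_id[i],
                                   sp$cell_class[i],
                                   sp$lib_size_meanlog[i], sp$lib_size_sdlog[i])
      }
      singlets <- do.call(cbind, cls_mat)
      truth_s <- tibble(
        sample_id = s,
        cell_class = rep(sp$cell_class, sp$n_cells),
        clone_id = rep(sp$clone_id, sp$n_cells),
        is_doublet = FALSE,
        parent_class_1 = NA_character_, parent_class_2 = NA_character_
      )
      n_total <- sum(sp$n_cells)
      n_dbl <- round(sp$doublet_fraction[1] * n_total)
      if (n_dbl > 0) {
        classes <- sp$cell_class
        dbl_mat <- matrix(0L, nrow = n_genes, ncol = n_dbl)
        p1 <- character(n_dbl); p2 <- character(n_dbl)
        for (j in seq_len(n_dbl)) {
          pick <- if (length(classes) >= 2) sample(length(classes), 2)
                  else c(1L, 1L)
          a <- pick[1]; b <- pick[2]
          ca <- draw_cells(1, sp$clone_id[a], sp$cell_class[a],
                           sp$lib_size_meanlog[a], sp$lib_size_sdlog[a])
          cb <- draw_cells(1, sp$clone_id[b], sp$cell_class[b],
                           sp$lib_size_meanlog[b], sp$lib_size_sdlog[b])
          dbl_mat[, j] <- ca[, 1] + cb[, 1]
          p1[j] <- sp$cell_class[a]; p2[j] <- sp$cell_class[b]
        }
        singlets <- cbind(singlets, dbl_mat)
        truth_s <- dplyr::bind_rows(truth_s, tibble(
          sample_id = s, cell_class = paste(p1, p2, sep = "+"),
          clone_id = NA_character_, is_doublet = TRUE,
          parent_class_1 = p1, parent_class_2 = p2
        ))
      }
      truth_s$cell_barcode <- sprintf("%s_cell%05d", s, seq_len(nrow(truth_s)))
      colnames(singlets) <- truth_s$cell_barcode
      blocks[[s]] <- singlets
      truth[[s]] <- truth_s
    }
    counts <- do.call(cbind, blocks)
    rownames(counts) <- annotation$gene_id
    truth <- dplyr::bind_rows(truth)
    truth <- truth[, c("cell_barcode", "sample_id", "cell_class", "clone_id",
                       "is_doublet", "parent_class_1", "parent_class_2")]
  })

  structure(
    list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      annotation = annotation,
      truth = truth,
      clones = clones,
      params = list(baseline_mean_shape = baseline_mean_shape,
                    dispersion = dispersion, mito_share = mito_share,
                    hk_boost = hk_boost,
                    marker_genes_per_class = marker_genes_per_class,
                    marker_boost = marker_boost, seed = seed)
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", length(unique(x$truth$sample_id)), " sample(s), ",
      sum(x$truth$is_doublet), " doublet(s)\n", sep = "")
  invisible(x)
}

#' Simulate read-level records for a single RNA-editing site
#'
#' Per cell, draws `Poisson(coverage_mean)` reads grouped into UMIs
#' (molecules). A molecule from an edited (sample, class) stratum carries
#' the alternate base with probability `edit_rate`; molecules elsewhere are
#' unedited. Each read reports its molecule's base, flipped to the
#' alternate base with probability `error_rate` when the molecule is
#' unedited (sequencing error). Phred base qualities are attached.
#'
#' @param truth Per-cell table with `cell_barcode`, `sample_id`,
#'   `cell_class` (e.g. the `truth` of a [simulate_tumor_counts()] run).
#' @param site A [site_spec()] giving reference and alternate base.
#' @param edited_classes Tibble with columns `sample_id`, `cell_class`
#'   naming the strata whose molecules are edited.
#' @param edit_rate Per-molecule editing probability in edited strata.
#' @param coverage_mean Mean reads per cell at the site.
#' @param error_rate Per-read probability that an unedited molecule is read
#'   as the alternate base.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `read_id`, `umi`, `cell_barcode`,
#'   `sample_id`, `base`, `base_quality`; the per-cell molecule-level
#'   ground truth (`n_umis`, `n_alt_umis`) is attached as attribute
#'   `"umi_truth"`.
#' @export
simulate_editing_reads <- function(truth, site, edited_classes,
                                   edit_rate, coverage_mean = 5,
                                   error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(site, "site_spec"))
  if (edit_rate < 0 || edit_rate > 1 || error_rate < 0 || error_rate > 1) {
    abort("edit_rate and error_rate must be probabilities in [0, 1]")
  }
  if (coverage_mean <= 0) abort("coverage_mean must be positive")
  empty <- tibble(read_id = character(), umi = character(),
                  cell_barcode = character(), sample_id = character(),
                  base = character(), base_quality = integer())
  if (is.null(truth) || nrow(truth) == 0) {
    attr(empty, "umi_truth") <- tibble(cell_barcode = character(),
                                       n_umis = integer(),
                                       n_alt_umis = integer())
    return(empty)
  }
  key <- paste(truth$sample_id, truth$cell_class)
  edited <- key %in% paste(edited_classes$sample_id, edited_classes$cell_class)

  with_seed(seed, {
    n_reads <- stats::rpois(nrow(truth), coverage_mean)
    rows <- vector("list", nrow(truth))
    umi_truth <- tibble(cell_barcode = truth$cell_barcode,
                        n_umis = 0L, n_alt_umis = 0L)
    for (i in seq_len(nrow(truth))) {
      r <- n_reads[i]
      if (r == 0) next
      # molecules: roughly 70% as many UMIs as reads, so some PCR duplicates
      n_mol <- max(1L, as.integer(ceiling(r * 0.7)))
      mol_of_read <- sample.int(n_mol, r, replace = TRUE)
      used <- sort(unique(mol_of_read))
      mol_edited <- stats::setNames(rep(FALSE, n_mol), seq_len(n_mol))
      if (edited[i] && edit_rate > 0) {
        mol_edited[used] <- stats::runif(length(used)) < edit_rate
      }
      read_edited <- mol_edited[mol_of_read]
      base <- ifelse(read_edited, site$alt_base,
                     ifelse(stats::runif(r) < error_rate,
                            site$alt_base, site$ref_base))
      qual <- pmin(41L, pmax(2L, as.integer(round(stats::rnorm(r, 36, 4)))))
      rows[[i]] <- tibble(
        umi = sprintf("u%04d", mol_of_read),
        cell_barcode = truth$cell_barcode[i],
        sample_id = truth$sample_id[i],
        base = base, base_quality = qual
      )
      umi_truth$n_umis[i] <- length(used)
      umi_truth$n_alt_umis[i] <- sum(mol_edited[used])
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) out <- empty
    else out <- tibble(read_id = sprintf("r%07d", seq_len(nrow(out))), out)
  })
  attr(out, "umi_truth") <- umi_truth
  out
}
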