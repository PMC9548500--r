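#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import Matrix
NULL

# Numeric-aware chromosome ordering: "1" < "2" < ... < "10" < "X" < "MT".
# Non-numeric labels sort alphabetically after all numeric ones, so the
# ordering is invariant to the input row order of the annotation.
chromosome_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

# Order gene annotation by (chromosome, start, gene_id); ties in start are
# broken by gene_id so the ordering is always well-defined.
order_annotation <- function(annotation) {
  lev <- chromosome_order(annotation$chromosome)
  ord <- order(match(annotation$chromosome, lev), annotation$start,
               annotation$gene_id)
  annotation[ord, , drop = FALSE]
}

check_annotation <- function(annotation) {
  needed <- c("gene_id", "chromosome", "start", "end")
  missing <- setdiff(needed, names(annotation))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(annotation$gene_id)) {
    abort("annotation gene_ids must be unique")
  }
  invisible(annotation)
}

# Seed handling: every stochastic function takes an explicit `seed` and
# restores the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
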