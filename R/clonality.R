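#' Pairwise Pearson correlation of mean CNA profiles
#'
#' The similarity statistic for the shared-origin test: standard Pearson
#' correlation between each unordered pair of per-group mean CNA vectors
#' over the common gene index.
#'
#' @param profiles A [mean_cna_profiles()] result, or a genes x groups
#'   numeric matrix.
#' @return A symmetric correlation matrix with unit diagonal. Groups with
#'   zero variance yield `NA` entries, with a warning.
#' @export
cna_correlation_matrix <- function(profiles) {
  mat <- if (inherits(profiles, "cna_profiles")) profiles$profiles
         else as.matrix(profiles)
  if (ncol(mat) < 2) abort("need at least 2 groups")
  if (nrow(mat) < 3) abort("common gene index must have length >= 3")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("zero-variance profile(s): ",
                paste(colnames(mat)[sds == 0], collapse = ", "),
                "; correlations reported as NA"))
  }
  r <- suppressWarnings(stats::cor(mat, method = "pearson"))
  diag(r) <- 1
  r
}

#' Null sample of unrelated-pair correlations
#'
#' Collects the off-diagonal correlations of all unordered group pairs
#' whose *both* members lie outside the tested set and which are not
#' designated as related (e.g. known primary/metastasis pairs). This is
#' the empirical null for "how similar are two unrelated tumors".
#'
#' @param r_matrix Symmetric correlation matrix with labelled dimnames.
#' @param related_pairs Tibble/data frame with two columns of labels (or
#'   `NULL`) naming known-related pairs to exclude.
#' @param tested_labels Labels of the tumors under investigation; any pair
#'   touching one of them is excluded from the null.
#' @return Numeric vector of null correlations, named `"a|b"`.
#' @export
null_distribution <- function(r_matrix, related_pairs = NULL,
                              tested_labels = character()) {
  labels <- colnames(r_matrix)
  if (is.null(labels)) abort("r_matrix must have dimnames")
  rel_key <- character()
  if (!is.null(related_pairs) && nrow(related_pairs) > 0) {
    a <- as.character(related_pairs[[1]]); b <- as.character(related_pairs[[2]])
    unknown <- setdiff(c(a, b), labels)
    if (length(unknown) > 0) {
      abort(paste0("related_pairs labels not in r_matrix: ",
                   paste(unknown, collapse = ", ")))
    }
    rel_key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  keep_lab <- setdiff(labels, tested_labels)
  out <- numeric(); nm <- character()
  for (i in seq_along(keep_lab)) {
    for (j in seq_along(keep_lab)) {
      if (j <= i) next
      key <- paste(min(keep_lab[i], keep_lab[j]),
                   max(keep_lab[i], keep_lab[j]), sep = "|")
      if (key %in% rel_key) next
      out <- c(out, r_matrix[keep_lab[i], keep_lab[j]])
      nm <- c(nm, key)
    }
  }
  if (length(out) == 0) abort("null distribution is empty: cannot test")
  stats::setNames(out, nm)
}

#' One-sided clonality p-values against the unrelated-pair null
#'
#' Tests whether an observed pair correlation is larger than expected for
#' unrelated tumors. `empirical` uses the plus-one rule
#' `p = (1 + #\{null >= r\}) / (1 + N)`; `gaussian` (default) fits a
#' normal to the null — after Fisher's z transform `atanh(r)` when
#' `fisher_z` — and reports the upper-tail probability, which can resolve
#' p-values finer than `1/(N + 1)`.
#'
#' @param r_obs Named numeric vector of observed pair correlations.
#' @param null_sample Numeric null from [null_distribution()].
#' @param method `"gaussian"` (default) or `"empirical"`.
#' @param fisher_z Apply `atanh` before the gaussian fit (default `TRUE`).
#' @return A tibble: `pair`, `r`, `p_value`, `method`.
#' @export
clonality_pvalues <- function(r_obs, null_sample,
                              method = c("gaussian", "empirical"),
                              fisher_z = TRUE) {
  method <- match.arg(method)
  if (length(null_sample) == 0) abort("null_sample is empty")
  if (method == "gaussian" && length(null_sample) < 3) {
    abort("gaussian method needs at least 3 null values")
  }
  p <- if (method == "empirical") {
    vapply(r_obs, function(r) {
      if (is.na(r)) return(NA_real_)
      (1 + sum(null_sample >= r)) / (1 + length(null_sample))
    }, numeric(1))
  } else {
    z_null <- if (fisher_z) atanh(pmin(pmax(null_sample, -1), 1)) else null_sample
    mu <- mean(z_null); sigma <- stats::sd(z_null)
    vapply(r_obs, function(r) {
      if (is.na(r)) return(NA_real_)
      z <- if (fisher_z) atanh(min(max(r, -1), 1)) else r
      stats::pnorm(z, mean = mu, sd = sigma, lower.tail = FALSE)
    }, numeric(1))
  }
  tibble(
    pair = names(r_obs) %||% as.character(seq_along(r_obs)),
    r = unname(r_obs), p_value = unname(p),
    method = if (method == "gaussian" && fisher_z) "gaussian_fisher_z"
             else method
  )
}

#' Test tumor pairs for shared clonal origin
#'
#' End-to-end wrapper: computes the pairwise Pearson correlation matrix of
#' mean CNA profiles, builds the unrelated-pair null (excluding tested
#' tumors and designated related pairs), and assigns one-sided p-values to
#' the tested pairs.
#'
#' @param profiles A [mean_cna_profiles()] result or genes x groups matrix.
#' @param tested_pairs Tibble/data frame with two label columns: the pairs
#'   whose shared origin is under test.
#' @param related_pairs Optional known-related pairs excluded from the
#'   null (the tested pairs are excluded automatically, as is any pair
#'   touching a tested tumor).
#' @param method,fisher_z Passed to [clonality_pvalues()].
#' @return An object of class `clonality_result` with elements `labels`,
#'   `r_matrix`, `null_sample`, `excluded_pairs`, `pvalues`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
test_clonality <- function(profiles, tested_pairs, related_pairs = NULL,
                           method = c("gaussian", "empirical"),
                           fisher_z = TRUE) {
  method <- match.arg(method)
  r <- cna_correlation_matrix(profiles)
  a <- as.character(tested_pairs[[1]]); b <- as.character(tested_pairs[[2]])
  unknown <- setdiff(c(a, b), colnames(r))
  if (length(unknown) > 0) {
    abort(paste0("tested labels not among profiles: ",
                 paste(unknown, collapse = ", ")))
  }
  tested_labels <- unique(c(a, b))
  null_sample <- null_distribution(r, related_pairs = related_pairs,
                                   tested_labels = tested_labels)
  r_obs <- stats::setNames(
    r[cbind(a, b)], paste(pmin(a, b), pmax(a, b), sep = "|"))
  pv <- clonality_pvalues(r_obs, null_sample, method = method,
                          fisher_z = fisher_z)
  excluded <- tibble(label_a = pmin(a, b), label_b = pmax(a, b),
                     role = "tested")
  if (!is.null(related_pairs) && nrow(related_pairs) > 0) {
    excluded <- dplyr::bind_rows(excluded, tibble(
      label_a = pmin(as.character(related_pairs[[1]]),
                     as.character(related_pairs[[2]])),
      label_b = pmax(as.character(related_pairs[[1]]),
                     as.character(related_pairs[[2]])),
      role = "related"))
  }
  structure(
    list(labels = colnames(r), r_matrix = r, null_sample = null_sample,
         excluded_pairs = excluded, pvalues = pv),
    class = "clonality_result"
  )
}

#' @export
print.clonality_result <- function(x, ...) {
  cat("<clonality_result> ", length(x$labels), " groups, null of ",
      length(x$null_sample), " unrelated pairs\n", sep = "")
  print(x$pvalues)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname test_clonality
#' @param x A `clonality_result`.
#' @param ... Unused.
#' @method tidy clonality_result
#' @export
tidy.clonality_result <- function(x, ...) x$pvalues

#' @rdname test_clonality
#' @method glance clonality_result
#' @export
glance.clonality_result <- function(x, ...) {
  tibble(
    n_groups = length(x$labels),
    n_null_pairs = length(x$null_sample),
    null_mean_r = mean(x$null_sample),
    null_sd_r = stats::sd(x$null_sample),
    method = x$pvalues$method[1]
  )
}
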