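#' Counts per million
#'
#' Library-size normalization: `count / (library_total * factor) * 1e6`.
#' Without normalization factors every column of the result sums to exactly
#' one million.
#'
#' @param counts Gene-by-library counts: a wide tibble with a `gene_id`
#'   column, or a numeric matrix with gene row names.
#' @param normalization_factors Optional named per-library factors, e.g. from
#'   [tmm_factors()].
#' @return A numeric matrix of CPM values (genes x libraries).
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b", "c"), L1 = c(1, 1, 2))
#' cpm(m)[, "L1"] # 250000 250000 500000
#' @export
cpm <- function(counts, normalization_factors = NULL) {
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("library with zero total counts: ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  if (!is.null(normalization_factors)) {
    if (!is.null(names(normalization_factors))) {
      normalization_factors <- normalization_factors[colnames(m)]
    }
    stopifnot(length(normalization_factors) == ncol(m),
              all(normalization_factors > 0))
    totals <- totals * normalization_factors
  }
  sweep(m, 2, totals, "/") * 1e6
}

as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else if (is.data.frame(counts)) {
    stopifnot("gene_id" %in% names(counts))
    m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
    rownames(m) <- counts$gene_id
  } else {
    abort("counts must be a matrix or a data frame with a gene_id column")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate gene ids")
  if (any(m < 0)) abort("counts must be nonnegative")
  m
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-library factors (the standard RNA-seq
#' scaling method), computed with edgeR: log-ratios against a reference
#' library (the one whose upper quartile is closest to the mean upper
#' quartile) are trimmed (30% on log-fold-changes, 5% on absolute
#' expression), averaged with precision weights, and the resulting factors
#' rescaled so their product is 1.
#'
#' @param counts As in [cpm()]; at least two libraries.
#' @return Named numeric vector of positive factors multiplying to 1.
#' @export
tmm_factors <- function(counts) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two libraries")
  keep <- rowSums(m) > 0
  f <- edgeR::calcNormFactors(m[keep, , drop = FALSE], method = "TMM")
  setNames(as.numeric(f), colnames(m))
}

#' Fold-change screen for differentially expressed genes
#'
#' The descriptive screen used for the sex comparison: TMM-adjusted CPM with
#' a pseudo-count of 0.5 per CPM value, genes kept when the mean CPM exceeds
#' `min_cpm` in at least one group and the group-mean ratio reaches
#' `min_fold` in either direction. Symmetric in its two groups up to fold
#' direction.
#'
#' @param counts As in [cpm()].
#' @param group_a,group_b Disjoint, non-empty character vectors of library
#'   ids.
#' @param min_cpm Expression floor (mean CPM must exceed this in a group).
#' @param min_fold Minimum fold change between group means.
#' @param use_tmm Apply TMM factors before CPM (default).
#' @return A tibble of passing genes with group means and the (a over b)
#'   fold change.
#' @export
deg_screen <- function(counts, group_a, group_b, min_cpm = 8, min_fold = 2,
                       use_tmm = TRUE) {
  m <- as_count_matrix(counts)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort("groups must be disjoint")
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing) > 0) {
    abort(paste0("unknown library id(s): ", paste(missing, collapse = ", ")))
  }
  x <- cpm(m, if (use_tmm) tmm_factors(m) else NULL)
  mean_a <- rowMeans(x[, group_a, drop = FALSE])
  mean_b <- rowMeans(x[, group_b, drop = FALSE])
  ratio <- (mean_a + 0.5) / (mean_b + 0.5)
  fold <- pmax(ratio, 1 / ratio)
  keep <- (mean_a > min_cpm | mean_b > min_cpm) & fold >= min_fold
  tibble(
    gene_id = rownames(x)[keep],
    mean_cpm_a = mean_a[keep],
    mean_cpm_b = mean_b[keep],
    fold_change = ratio[keep],
    direction = if_else(ratio[keep] >= 1, "up_in_a", "up_in_b")
  ) %>% arrange(dplyr::desc(.data$fold_change))
}

#' Spearman-correlation distance matrix between libraries
#'
#' Pairwise dissimilarity `1 - r`, where `r` is the Spearman rank correlation
#' between the expression profiles of two libraries, computed over genes
#' whose mean (TMM-adjusted) CPM exceeds `min_mean_cpm`. Ties receive average
#' ranks. Values lie in `[0, 2]`; the matrix is symmetric with a zero
#' diagonal.
#'
#' @param counts As in [cpm()]; at least two libraries.
#' @param min_mean_cpm Mean-CPM expression filter: only genes with average
#'   CPM above this enter the profile comparison.
#' @param use_tmm Apply TMM factors before the CPM filter (ranks within a
#'   library, and hence the correlations, are unaffected by per-library
#'   scaling; only the filter is).
#' @return A symmetric numeric matrix of class `spearman_dist`.
#' @export
spearman_distance <- function(counts, min_mean_cpm = 16, use_tmm = TRUE) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("need at least two libraries")
  x <- cpm(m, if (use_tmm) tmm_factors(m) else NULL)
  keep <- rowMeans(x) > min_mean_cpm
  if (sum(keep) < 2) {
    abort(sprintf("only %d gene(s) pass the mean-CPM filter; need at least 2",
                  sum(keep)))
  }
  d <- 1 - cor(x[keep, , drop = FALSE], method = "spearman")
  structure(d, class = c("spearman_dist", class(d)))
}

#' @export
print.spearman_dist <- function(x, ...) {
  cat("Spearman-correlation distance (1 - rho) between libraries\n")
  print(unclass(x), ...)
  invisible(x)
}
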