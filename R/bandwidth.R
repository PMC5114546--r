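#' Dyadic bandwidth grid
#'
#' h_s = 2^{2(s - 23) / (5 + k)} for s = 1..S, a strictly increasing
#' geometric grid passing through h = 1 at s = 23. With the defaults
#' S = 30 and k = 10 PCs the grid spans roughly 0.131 to 1.91 on the
#' [0, 1] PC scale.
#'
#' @param S number of grid points (default 30).
#' @param k number of PC dimensions (default 10).
#' @return numeric vector of length S, strictly increasing.
#' @export
bandwidth_grid <- function(S = 30, k = 10) {
  stopifnot(S >= 1, k >= 1)
  2^(2 * (seq_len(S) - 23) / (5 + k))
}

#' Kolmogorov distance of p-values from the uniform distribution
#'
#' The two-sided sup discrepancy between the empirical distribution of
#' the p-values and the uniform CDF, computed exactly over the order
#' statistics: max_i max(i/L - p_(i), p_(i) - (i - 1)/L). Lies in [0, 1]
#' and is invariant to permutation of the input.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return the Kolmogorov statistic.
#' @export
kolmogorov_uniform <- function(pvals) {
  L <- length(pvals)
  if (L == 0) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  p <- sort(pvals)
  i <- seq_len(L)
  max(pmax(i / L - p, p - (i - 1) / L))
}

#' Select the smoothing bandwidth by p-value uniformity
#'
#' For each candidate h, performs the PC-nonp single-variant score test
#' at every background genomic marker (the same markers used for the
#' PCs): the trait and all marker columns are residualized once under h,
#' and the resulting L p-values are scored by their Kolmogorov distance
#' Kol(h) from uniformity. The selected h* minimizes Kol(h); if
#' population stratification is fully corrected at some h, the marker
#' p-values are uniform under the null and Kol(h) is small. Ties are
#' broken toward the larger h (the milder adjustment). h* is computed
#' once per dataset and reused for every candidate-locus test.
#'
#' Each bandwidth costs one n x n weight matrix and one pass over the
#' markers, so the search is linear in the grid size.
#'
#' @param y trait vector (quantitative or 0/1).
#' @param markers background [genotype_matrix()] (monomorphic columns are
#'   skipped with a message).
#' @param pcs rescaled `pc_matrix` computed from the same markers.
#' @param grid candidate bandwidths, strictly increasing (default
#'   [bandwidth_grid()] for `pcs$k` dimensions).
#' @param subsample optionally evaluate Kol(h) on this many uniformly
#'   subsampled markers (NULL = all); the p-value distribution, not the
#'   marker identity, is what matters.
#' @return object of class `bandwidth_selection`: list with `grid`,
#'   `kol` (per-h statistic), `h_star`, `s_star` (grid index) and
#'   `pvals_at_star`.
#' @export
select_bandwidth <- function(y, markers, pcs, grid = NULL, subsample = NULL) {
  stopifnot(inherits(markers, "genotype_matrix"))
  if (is.null(grid)) grid <- bandwidth_grid(k = pcs$k)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  M <- markers$values
  poly <- markers$maf > 0
  if (!all(poly)) {
    message(sum(!poly), " monomorphic marker(s) skipped in bandwidth selection")
    M <- M[, poly, drop = FALSE]
  }
  if (ncol(M) == 0) stop("no polymorphic markers left for bandwidth selection")
  if (!is.null(subsample) && subsample < ncol(M)) {
    M <- M[, round(seq(1, ncol(M), length.out = subsample)), drop = FALSE]
  }
  kol <- numeric(length(grid))
  best <- NULL
  for (s in seq_along(grid)) {
    sm <- nw_smoother(pcs, grid[s])
    p <- marker_pvalues_sm(y, M, sm)
    kol[s] <- kolmogorov_uniform(p)
    if (is.null(best) || kol[s] <= best$kol) {
      best <- list(kol = kol[s], s = s, pvals = p)
    }
  }
  structure(list(grid = grid, kol = kol, h_star = grid[best$s],
                 s_star = best$s, pvals_at_star = best$pvals),
            class = "bandwidth_selection")
}

# Single-variant score-test p-values for all columns of M, after
# residualizing trait and genotypes with a prebuilt smoother.
marker_pvalues_sm <- function(y, M, sm) {
  y_res <- residualize_sm(y, sm)
  M_res <- residualize_sm(M, sm)
  n <- length(y)
  U <- drop(crossprod(M_res, y_res))
  V <- sum(y_res^2) * colSums(M_res^2) / n
  stat <- ifelse(V > 0, U^2 / V, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @export
print.bandwidth_selection <- function(x, ...) {
  cat(sprintf("bandwidth_selection: %d-point grid [%.4g, %.4g]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  h* = %.5g (s = %d), Kol(h*) = %.5g\n",
              x$h_star, x$s_star, x$kol[x$s_star]))
  invisible(x)
}

#' Write the bandwidth search as TSV
#'
#' Emits one row per grid point: s, h, kol, selected flag.
#'
#' @param sel a `bandwidth_selection`.
#' @param path output file.
#' @export
write_bandwidth_tsv <- function(sel, path) {
  df <- data.frame(s = seq_along(sel$grid), h = sel$grid, kol = sel$kol,
                   selected = seq_along(sel$grid) == sel$s_star)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
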