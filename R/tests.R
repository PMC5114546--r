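#' Score test on adjusted trait and genotype vectors
#'
#' T = U^2 / V with U = sum_i y_i x_i and V = (sum y_i^2)(sum x_i^2) / n,
#' so on mean-centered inputs T = n r^2 with r the Pearson correlation.
#' Under the null of no association T is asymptotically chi-square with
#' one degree of freedom. Both inputs are expected to be already adjusted
#' (residualized or centered); the statistic is invariant to rescaling of
#' either vector.
#'
#' @param y_adj adjusted trait values.
#' @param x_adj adjusted genotype scores (same length).
#' @param method label recorded in the result.
#' @param mode `"single_variant"` or `"regional"`.
#' @return a `pcnonp_test` object: list with `method`, `mode`, `statistic`
#'   (chi-square, 1 df), `pvalue`, and `untestable` (TRUE when x_adj is
#'   identically zero, e.g. a variant monomorphic after adjustment; then
#'   statistic = 0 and pvalue = 1).
#' @export
score_test <- function(y_adj, x_adj, method = "score", mode = "single_variant") {
  if (length(y_adj) != length(x_adj)) stop("y_adj and x_adj lengths differ")
  n <- length(y_adj)
  if (n < 3) stop("need at least 3 observations")
  sxx <- sum(x_adj^2)
  syy <- sum(y_adj^2)
  if (sxx == 0 || syy == 0) {
    return(new_test_result(method, mode, 0, 1, untestable = TRUE))
  }
  U <- sum(y_adj * x_adj)
  V <- syy * sxx / n
  stat <- U^2 / V
  new_test_result(method, mode, stat,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

new_test_result <- function(method, mode, statistic, pvalue,
                            untestable = FALSE) {
  structure(list(method = method, mode = mode, statistic = statistic,
                 pvalue = pvalue, untestable = untestable),
            class = "pcnonp_test")
}

#' @export
print.pcnonp_test <- function(x, ...) {
  cat(sprintf("%s (%s): chi-square(1) = %.4g, p = %.4g%s\n", x$method,
              x$mode, x$statistic, x$pvalue,
              if (x$untestable) " [untestable]" else ""))
  invisible(x)
}

#' Uncorrected association score test
#'
#' The score test applied to the raw (mean-centered) trait and genotype
#' vectors, with no stratification adjustment. Serves as the baseline
#' comparison: it is the h -> Inf limit of [pc_nonp_test()].
#'
#' @param y trait values (quantitative, or 0/1 affection status).
#' @param x genotype scores.
#' @param mode see [score_test()].
#' @return a `pcnonp_test`.
#' @export
uncorrected_test <- function(y, x, mode = "single_variant") {
  score_test(y - mean(y), x - mean(x), method = "Uncorrected", mode = mode)
}

#' Genomic-control adjustment of a test statistic
#'
#' Estimates the inflation factor lambda = median(T_l) / 0.456 from the
#' chi-square statistics of the same test applied to genome-wide null
#' markers (the Devlin-Roeder convention; 0.456 is the median of the
#' chi-square distribution with 1 df), floors it at 1, and divides the
#' candidate statistic by it.
#'
#' @param candidate a `pcnonp_test` for the candidate locus.
#' @param marker_stats chi-square statistics at the L genomic markers.
#' @return a `pcnonp_test` with method `"GC"`, plus a `lambda` field.
#' @export
gc_correct <- function(candidate, marker_stats) {
  if (length(marker_stats) == 0) stop("marker_stats must be nonempty")
  lambda <- max(1, stats::median(marker_stats) / 0.456)
  stat <- candidate$statistic / lambda
  out <- new_test_result("GC", candidate$mode, stat,
                         stats::pchisq(stat, df = 1, lower.tail = FALSE),
                         untestable = candidate$untestable)
  out$lambda <- lambda
  out
}

#' Linear-PC corrected score test
#'
#' Residualizes trait and genotype on an intercept plus the k ancestry PC
#' columns by least squares, then applies the score test. This is the
#' standard linear principal-component correction that PC-nonp
#' generalizes.
#'
#' @param y trait values.
#' @param x genotype scores.
#' @param pcs a `pc_matrix` (rescaled or raw; least squares is invariant
#'   to affine transformations of the columns).
#' @param mode see [score_test()].
#' @return a `pcnonp_test` with method `"PC-linear"`.
#' @export
pc_linear_test <- function(y, x, pcs, mode = "single_variant") {
  P <- if (inherits(pcs, "pc_matrix")) pcs$coords else as.matrix(pcs)
  n <- length(y)
  if (n <= ncol(P) + 1) stop("need n > k + 1 observations")
  Q <- pc_projection_basis(P)
  y_res <- y - Q %*% crossprod(Q, y)
  x_res <- x - Q %*% crossprod(Q, x)
  score_test(drop(y_res), drop(x_res), method = "PC-linear", mode = mode)
}

# Orthonormal basis of span(1, PCs); collinear columns are dropped with a
# message so rank-deficient PC sets degrade gracefully.
pc_projection_basis <- function(P) {
  X <- cbind(1, P)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    message(ncol(X) - qr_x$rank, " collinear PC column(s) dropped")
  }
  qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
}

#' Madsen-Browning weighted regional genotype score
#'
#' Collapses the variants of a genomic region into one score per
#' individual, x_i = sum_m w_m g_im, with w_m = 1 / sqrt(n q_m (1 - q_m))
#' and q_m = (sum_i g_im + 1) / (2n + 2). The +1/+2 pseudo-count keeps
#' weights finite for monomorphic variants; rarer variants receive larger
#' weights.
#'
#' @param region a [genotype_matrix()] (or plain 0/1/2 matrix) of the
#'   region's variants.
#' @return length-n numeric vector of combined genotype scores.
#' @export
regional_score <- function(region) {
  G <- if (inherits(region, "genotype_matrix")) region$values else
    as.matrix(region)
  if (ncol(G) < 1) stop("region must contain at least one variant")
  n <- nrow(G)
  q <- (colSums(G) + 1) / (2 * n + 2)
  w <- 1 / sqrt(n * q * (1 - q))
  drop(G %*% w)
}

#' PC-nonp association test
#'
#' The proposed test: trait and genotype score are each residualized by a
#' quartic-kernel Nadaraya-Watson regression on the rescaled ancestry PCs
#' at a common bandwidth (normally the h* chosen by
#' [select_bandwidth()]), and the score test is applied to the residual
#' pair. For a regional test pass `x = regional_score(region)`.
#'
#' @param y trait values.
#' @param x genotype score vector (single variant, or combined regional
#'   score).
#' @param pcs rescaled `pc_matrix`.
#' @param h bandwidth, typically `select_bandwidth(...)$h_star`.
#' @param mode see [score_test()].
#' @return a `pcnonp_test` with method `"PC-nonp"` and field `h_used`.
#' @export
pc_nonp_test <- function(y, x, pcs, h, mode = "single_variant") {
  if (stats::var(x) == 0) {  # constant before (hence after) adjustment
    out <- new_test_result("PC-nonp", mode, 0, 1, untestable = TRUE)
    out$h_used <- h
    return(out)
  }
  sm <- nw_smoother(pcs, h)
  out <- score_test(residualize_sm(y, sm), residualize_sm(x, sm),
                    method = "PC-nonp", mode = mode)
  out$h_used <- h
  out
}

#' Write test results to TSV
#'
#' @param results a list of `pcnonp_test` objects, optionally named by
#'   variant or region id.
#' @param path output file.
#' @export
write_results_tsv <- function(results, path) {
  ids <- names(results) %||% paste0("locus", seq_along(results))
  df <- data.frame(
    id = ids,
    method = vapply(results, `[[`, "", "method"),
    mode = vapply(results, `[[`, "", "mode"),
    statistic = vapply(results, `[[`, 0, "statistic"),
    pvalue = vapply(results, `[[`, 0, "pvalue")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
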