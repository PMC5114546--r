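#' Ancestry principal components of background markers
#'
#' Computes the leading left singular vectors of the column-standardized
#' genotype matrix at genomic markers. Each marker column is centered by
#' its mean 2q and divided by sqrt(q(1 - q)) with q the sample allele
#' frequency, the usual normalization for ancestry PCA of SNP data.
#' Monomorphic markers carry no ancestry information and are dropped
#' (with a message giving the count) before standardization.
#'
#' The sign of each component is fixed so that the entry of largest
#' absolute value is positive, making the output deterministic across
#' numerical backends.
#'
#' @param markers a [genotype_matrix()] of background genomic markers.
#' @param k number of components to retain (default 10).
#' @return An object of class `pc_matrix`: list with `coords` (n x k,
#'   raw sample coordinates), `k` and `explained` (share of each singular
#'   value in the total). Use [rescale_unit_interval()] to map the
#'   coordinates to [0, 1] before kernel smoothing.
#' @seealso [rescale_unit_interval()], [ancestry_pcs()]
#' @export
compute_pcs <- function(markers, k = 10) {
  stopifnot(inherits(markers, "genotype_matrix"), k >= 1)
  G <- markers$values
  n <- nrow(G)
  q <- colMeans(G) / 2
  poly <- q > 0 & q < 1 & (colMeans(G^2) - (2 * q)^2 > 0)
  if (!all(poly)) {
    message(sum(!poly), " monomorphic marker(s) dropped before PCA")
    G <- G[, poly, drop = FALSE]
    q <- q[poly]
  }
  if (ncol(G) == 0) stop("all markers are monomorphic; PCA is undefined")
  if (k > min(n, ncol(G))) {
    stop(sprintf("k = %d exceeds the achievable rank min(n, m) = %d",
                 k, min(n, ncol(G))))
  }
  Z <- sweep(G, 2, 2 * q, "-")
  Z <- sweep(Z, 2, sqrt(q * (1 - q)), "/")
  sv <- svd(Z, nu = k, nv = 0)
  if (sum(sv$d > sv$d[1] * 1e-12) < k) {
    stop(sprintf("k = %d exceeds the numerical rank %d of the marker matrix",
                 k, sum(sv$d > sv$d[1] * 1e-12)))
  }
  U <- sv$u
  for (j in seq_len(k)) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("PC", seq_len(k))
  rownames(U) <- markers$sample_ids
  structure(list(coords = U, k = k, explained = sv$d[seq_len(k)] / sum(sv$d)),
            class = "pc_matrix")
}

#' Rescale principal components to the unit interval
#'
#' Maps each column v to (v - min) / (max - min) so every ancestry
#' coordinate lies in [0, 1], the scale on which the common kernel
#' bandwidth h is defined. Rank order within each column is preserved and
#' the map is invariant to affine transformations of the input column.
#'
#' @param pcs a `pc_matrix` (or plain matrix of PC coordinates).
#' @return a `pc_matrix` whose columns each span exactly [0, 1].
#' @export
rescale_unit_interval <- function(pcs) {
  coords <- if (inherits(pcs, "pc_matrix")) pcs$coords else as.matrix(pcs)
  rng <- apply(coords, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop("constant PC column cannot be rescaled to [0, 1]")
  }
  coords <- sweep(sweep(coords, 2, rng[1, ], "-"), 2, span, "/")
  out <- if (inherits(pcs, "pc_matrix")) pcs else list(coords = NULL,
                                                       k = ncol(coords),
                                                       explained = NULL)
  out$coords <- coords
  class(out) <- "pc_matrix"
  out
}

#' Compute and rescale ancestry PCs in one step
#'
#' Convenience wrapper: [compute_pcs()] followed by
#' [rescale_unit_interval()], yielding the covariates used by the kernel
#' smoother.
#'
#' @inheritParams compute_pcs
#' @return a rescaled `pc_matrix`.
#' @export
ancestry_pcs <- function(markers, k = 10) {
  rescale_unit_interval(compute_pcs(markers, k))
}

#' @export
print.pc_matrix <- function(x, ...) {
  cat(sprintf("pc_matrix: %d samples x %d components\n",
              nrow(x$coords), x$k))
  if (!is.null(x$explained)) {
    cat("  singular-value share:",
        paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write PC coordinates as TSV
#'
#' @param pcs a `pc_matrix`.
#' @param path output path; columns are sample_id, PC1..PCk.
#' @export
write_pcs_tsv <- function(pcs, path) {
  df <- data.frame(sample_id = rownames(pcs$coords) %||%
                     paste0("S", seq_len(nrow(pcs$coords))),
                   pcs$coords, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
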