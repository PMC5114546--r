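#' Quartic (biweight) kernel
#'
#' K(u) = (15/16) (1 - u^2)^2 on |u| <= 1 and 0 outside. Integrates to 1,
#' is even, and attains its maximum 15/16 at u = 0.
#'
#' @param u numeric vector of scaled distances.
#' @return kernel weights, same shape as `u`.
#' @examples
#' quartic_kernel(0)      # 0.9375
#' quartic_kernel(c(-1, 1, 2))  # all zero
#' @export
quartic_kernel <- function(u) {
  u2 <- pmin(u * u, 1)
  (15 / 16) * (1 - u2)^2
}

#' Product-kernel weight matrix over PC coordinates
#'
#' W[i, j] = prod_d K((p_id - p_jd) / h) with K the quartic kernel and a
#' single common bandwidth h shared by all k dimensions. The 1/h^k
#' normalizing constant is omitted: it cancels in the Nadaraya-Watson
#' ratio, so weight matrices are comparable across h only through that
#' ratio. The matrix is symmetric with diagonal (15/16)^k > 0, which
#' guarantees a positive denominator in the smoother for every sample.
#'
#' @param pcs a `pc_matrix` with columns in [0, 1] (see
#'   [rescale_unit_interval()]), or a plain matrix.
#' @param h common bandwidth, > 0, on the [0, 1] PC scale.
#' @return n x n nonnegative symmetric weight matrix.
#' @export
pairwise_weights <- function(pcs, h) {
  if (h <= 0) stop("bandwidth h must be positive")
  P <- if (inherits(pcs, "pc_matrix")) pcs$coords else as.matrix(pcs)
  W <- NULL
  for (d in seq_len(ncol(P))) {
    Kd <- quartic_kernel(outer(P[, d], P[, d], "-") / h)
    W <- if (is.null(W)) Kd else W * Kd
  }
  W
}

# Internal: smoother state reused across many vectors at one bandwidth.
# Builds the weight matrix once; fitting a vector is then one
# matrix-vector product (or one matrix product for a batch).
nw_smoother <- function(pcs, h) {
  W <- pairwise_weights(pcs, h)
  list(W = W, rs = rowSums(W), h = h)
}

#' Nadaraya-Watson fit on ancestry coordinates
#'
#' fitted[i] = sum_j W[i, j] v[j] / sum_j W[i, j]: the kernel-weighted mean
#' of `values` over individuals whose ancestry coordinates are within h of
#' individual i in every PC dimension. Self-weights are included, so the
#' denominator is always positive; fitted values lie inside the range of
#' `values`.
#'
#' @param values numeric vector (or n x m matrix of columns to fit jointly).
#' @param pcs `pc_matrix` of rescaled ancestry coordinates.
#' @param h common bandwidth (> 0).
#' @return fitted values, same shape as `values`.
#' @export
nw_fit <- function(values, pcs, h) {
  sm <- nw_smoother(pcs, h)
  nw_fit_sm(values, sm)
}

nw_fit_sm <- function(values, sm) {
  n <- length(sm$rs)
  if (is.matrix(values)) {
    if (nrow(values) != n) stop("values rows must match the PC matrix")
    (sm$W %*% values) / sm$rs
  } else {
    if (length(values) != n) stop("values length must match the PC matrix")
    drop(sm$W %*% values) / sm$rs
  }
}

#' Residuals of the kernel regression on ancestry PCs
#'
#' `values - nw_fit(values, pcs, h)`: the trait or genotype score after
#' removing its kernel-smooth dependence on ancestry. The smoother is
#' linear, so residualization is linear too, and a constant vector maps
#' to zero.
#'
#' @inheritParams nw_fit
#' @return residual vector (or matrix), same shape as `values`.
#' @export
residualize <- function(values, pcs, h) {
  values - nw_fit(values, pcs, h)
}

residualize_sm <- function(values, sm) {
  values - nw_fit_sm(values, sm)
}
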