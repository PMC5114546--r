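# Small fixture builders shared across test files.

# genotype matrix with polymorphic columns
random_genotypes <- function(n, m, maf = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    G <- matrix(rbinom(n * m, 2, maf), n, m)
    if (all(colSums(G) > 0 & colSums(G) < 2 * n)) break
  }
  genotype_matrix(G)
}

# deterministic 1-D PC layout on [0, 1]
line_pcs <- function(p) {
  structure(list(coords = matrix(p, ncol = 1), k = 1, explained = 1),
            class = "pc_matrix")
}

pc_from_matrix <- function(P) {
  structure(list(coords = as.matrix(P), k = ncol(as.matrix(P)),
                 explained = NULL),
            class = "pc_matrix")
}

# naive O(n^2 k) double-loop Nadaraya-Watson oracle
nw_oracle <- function(values, P, h) {
  n <- nrow(P)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      w <- 1
      for (d in seq_len(ncol(P))) {
        u <- (P[i, d] - P[j, d]) / h
        w <- w * if (abs(u) <= 1) (15 / 16) * (1 - u^2)^2 else 0
      }
      num <- num + w * values[j]
      den <- den + w
    }
    fitted[i] <- num / den
  }
  fitted
}

# brute-force sup-discrepancy between the ECDF and the uniform CDF,
# evaluated on both sides of every jump point
kolmogorov_oracle <- function(p) {
  Fn <- stats::ecdf(p)
  eps <- 1e-12
  m <- 0
  for (x in sort(unique(c(0, p, 1)))) {
    m <- max(m, abs(Fn(x) - x), abs(Fn(max(x - eps, 0)) - max(x - eps, 0)))
  }
  m
}
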