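test_that("the built-in MAF spectrum mixes rare and common as specified", {
  set.seed(101)
  p <- sample_ancestral_maf(100000)
  expect_true(all(p > 0 & p <= 0.5))
  expect_lt(abs(mean(p < 0.01) - 0.6), 0.01)
  # degenerate user spectrum
  expect_equal(sample_ancestral_maf(5, spectrum = 0.03), rep(0.03, 5))
  expect_error(sample_ancestral_maf(1, spectrum = numeric(0)), "empty")
})

test_that("Balding-Nichols draws have mean p and variance p(1-p)Fst", {
  set.seed(103)
  p <- 0.1
  fst <- 0.01
  draws <- replicate(100, balding_nichols_freqs(p, fst, 1000))
  expect_lt(abs(mean(draws) - p), 0.005)
  expect_lt(abs(var(c(draws)) / (p * (1 - p) * fst) - 1), 0.15)
  # fst -> 0 concentrates at p
  tight <- balding_nichols_freqs(0.3, 1e-6, 50)
  expect_true(all(abs(tight - 0.3) < 0.01))
  # acceptance rule guarantees the threshold
  f <- replicate(200, max(balding_nichols_freqs(0.001, 0.01, 5,
                                                min_freq = 0.002)))
  expect_true(all(f >= 0.002))
})

test_that("Hardy-Weinberg genotype sampling respects subpopulation freqs", {
  set.seed(107)
  labels <- rep(1:2, each = 5000)
  g <- genotypes_from_freqs(c(0, 1), labels)
  expect_true(all(g[labels == 1] == 0))
  expect_true(all(g[labels == 2] == 2))
  g2 <- genotypes_from_freqs(c(0.2, 0.6), labels)
  se <- sqrt(0.2 * 0.8 / (2 * 5000))
  expect_lt(abs(mean(g2[labels == 1]) / 2 - 0.2), 3 * se)
})

test_that("null traits carry the configured subpopulation means", {
  set.seed(109)
  labels <- rep(1:2, each = 4000)
  y <- null_trait_quant(labels, k0 = 2, mu = 2)
  d <- mean(y[labels == 2]) - mean(y[labels == 1])
  expect_lt(abs(d - 2), 3 * sqrt(2 / 4000))
  expect_lt(abs(var(y[labels == 1]) - 1), 0.1)
  # k0 = 1 is standard normal
  y1 <- null_trait_quant(rep(1, 4000), k0 = 1)
  expect_lt(abs(mean(y1)), 3 / sqrt(4000))
  # k0 > 2 means evenly spaced on [0, mu]
  y20 <- null_trait_quant(rep(1:20, each = 2000), k0 = 20, mu = 5)
  m <- tapply(y20, rep(1:20, each = 2000), mean)
  expect_equal(as.vector(m), 5 * (0:19) / 19, tolerance = 0.15)
})

test_that("equal-heritability effects: ratio, variance share, null limit", {
  # beta ratio for q = 0.005 vs 0.02 at equal per-variant heritability
  b <- sqrt((0.01 / 2) / (2 * c(0.005, 0.02) * (1 - c(0.005, 0.02))))
  expect_equal(b[1] / b[2], 1.985, tolerance = 1e-3)
  set.seed(113)
  n <- 100000
  q <- c(0.05, 0.2)
  G <- cbind(rbinom(n, 2, q[1]), rbinom(n, 2, q[2]))
  y0 <- rnorm(n)
  h2 <- 0.2
  y <- power_trait(G, 1:2, h2, y0, maf = q)
  gen_var <- var(y - y0)
  expect_lt(abs(gen_var - h2), 0.01)            # absolute genetic variance
  expect_lt(abs(gen_var / var(y) - h2 / (1 + h2)), 0.01)
  expect_identical(power_trait(G, 1:2, 0, y0, maf = q), y0)
  expect_error(power_trait(G, 1:2, 1.2, y0), "h2")
})

test_that("liability threshold yields ~16% prevalence and is affine-invariant", {
  set.seed(127)
  y <- rnorm(200000)
  prev <- mean(dichotomize(y))
  expect_lt(abs(prev - pnorm(1, lower.tail = FALSE)), 0.004)
  expect_equal(dichotomize(c(0, 0, 0, 10)), c(0L, 0L, 0L, 1L))
  expect_equal(dichotomize(3 - 2 * y[1:1000]), dichotomize(-y[1:1000]))
  expect_error(dichotomize(rep(1, 5)), "variance")
})

test_that("simulated cohorts recover the input Fst", {
  set.seed(131)
  cfg <- subpop_config(k0 = 5, fst = 0.01, n_per_subpop = 10, L = 10000)
  co <- simulate_subpop(cfg)
  f <- co$truth$marker_freqs          # k0 x L generating frequencies
  p <- co$truth$marker_p
  keep <- p > 0.05                    # Fst moments are noisy at tiny p
  ratio <- apply(f[, keep], 2, var) / (p[keep] * (1 - p[keep]))
  expect_lt(abs(mean(ratio) - 0.01), 0.002)
})

test_that("cohort pieces are consistent", {
  set.seed(137)
  cfg <- subpop_config(k0 = 3, n_per_subpop = 20, L = 50, n_T = 8)
  co <- simulate_subpop(cfg)
  expect_equal(length(co$trait), 60)
  expect_equal(length(co$causal_ids), 4)
  expect_true(all(co$causal_ids %in% 1:8))
  expect_equal(nrow(co$markers$values), nrow(co$region$values))
  expect_equal(co$markers$sample_ids, co$region$sample_ids)
})
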