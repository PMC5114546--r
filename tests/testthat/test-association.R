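test_that("score statistic equals n on identical centered inputs", {
  set.seed(1)
  y <- rnorm(25)
  y <- y - mean(y)
  r <- score_test(y, y)
  expect_equal(r$statistic, 25)
})

test_that("orthogonal inputs give T = 0 and p = 1", {
  y <- c(1, -1, 1, -1)
  x <- c(1, 1, -1, -1)
  r <- score_test(y, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)
})

test_that("score statistic equals n * r^2 on centered inputs", {
  set.seed(3)
  for (trial in 1:5) {
    n <- sample(10:200, 1)
    y <- rnorm(n); y <- y - mean(y)
    x <- rnorm(n); x <- x - mean(x)
    expect_equal(score_test(y, x)$statistic, n * cor(y, x)^2,
                 tolerance = 1e-10)
  }
})

test_that("score statistic is invariant to rescaling either input", {
  set.seed(5)
  y <- rnorm(30); x <- rnorm(30)
  t0 <- score_test(y, x)$statistic
  expect_equal(score_test(2.3 * y, x)$statistic, t0)
  expect_equal(score_test(y, -0.7 * x)$statistic, t0)
})

test_that("untestable candidates are flagged with p = 1", {
  r <- score_test(rnorm(10), rep(0, 10))
  expect_true(r$untestable)
  expect_equal(r$pvalue, 1)
})

test_that("genomic control floors lambda at 1 and scales the statistic", {
  cand <- score_test(c(1, -1, 2, -2), c(1, -1, 1, -1))
  g1 <- gc_correct(cand, rep(0.456, 5))
  expect_equal(g1$lambda, 1)
  expect_equal(g1$statistic, cand$statistic)
  g2 <- gc_correct(cand, c(0.912, 0.912, 0.912))
  expect_equal(g2$lambda, 2)
  expect_equal(g2$statistic, cand$statistic / 2)
  # deflation is floored: lambda never < 1
  g3 <- gc_correct(cand, rep(0.1, 9))
  expect_equal(g3$lambda, 1)
  expect_error(gc_correct(cand, numeric(0)), "nonempty")
  # chi-square(1) marker statistics give lambda near 1
  set.seed(7)
  stats <- rchisq(100000, 1)
  expect_lt(abs(median(stats) / 0.456 - 1), 0.02)
})

test_that("PC-linear matches a brute-force normal-equations oracle", {
  set.seed(9)
  n <- 8
  P <- matrix(runif(n * 2), n, 2)
  y <- rnorm(n); x <- rbinom(n, 2, 0.4) + rnorm(n, sd = 1e-6)
  X <- cbind(1, P)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  r_or <- score_test(drop((diag(n) - H) %*% y), drop((diag(n) - H) %*% x))
  r_pl <- pc_linear_test(y, x, pc_from_matrix(P))
  expect_equal(r_pl$statistic, r_or$statistic, tolerance = 1e-8)
})

test_that("PC-linear degenerates correctly", {
  set.seed(11)
  n <- 30
  P <- matrix(runif(n), n, 1)
  y_lin <- 2 + 3 * P[, 1]           # exactly linear in PC1
  x <- rbinom(n, 2, 0.3)
  y_res <- residuals(lm(y_lin ~ P))
  expect_lt(max(abs(y_res)), 1e-10) # regression absorbs y completely
  r <- score_test(rep(0, n), x - mean(x))
  expect_equal(r$statistic, 0)      # degenerate trait: no association
  expect_true(r$untestable)
  # PCs orthogonal to y and x reduce to the uncorrected test
  y <- rnorm(n); y <- y - mean(y)
  x2 <- rnorm(n); x2 <- x2 - mean(x2)
  Po <- matrix(rnorm(n * 2), n, 2)
  Q <- qr.Q(qr(cbind(1, y, x2)))
  Po <- Po - Q %*% crossprod(Q, Po)  # orthogonal to 1, y and x2
  r1 <- pc_linear_test(y, x2, pc_from_matrix(Po))
  r2 <- uncorrected_test(y, x2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
})

test_that("Madsen-Browning weights favor rarer variants", {
  G <- matrix(c(0, 0, 1, 1), 4, 1)
  x <- regional_score(G)
  w <- 1 / sqrt(4 * 0.3 * 0.7)
  expect_equal(x, c(0, 0, w, w))
  expect_equal(w, 1.0911, tolerance = 1e-4)
  # single-variant region is proportional to its genotypes
  g <- c(0, 1, 2, 1)
  expect_equal(regional_score(matrix(g)), g * regional_score(matrix(g))[2])
  # rarer variant gets the larger weight
  set.seed(13)
  n <- 2000
  G2 <- cbind(rbinom(n, 2, 0.005), rbinom(n, 2, 0.05))
  q <- (colSums(G2) + 1) / (2 * n + 2)
  w2 <- 1 / sqrt(n * q * (1 - q))
  expect_gt(w2[1], w2[2])
  # monomorphic column keeps a finite weight via the pseudo-count
  expect_true(all(is.finite(regional_score(matrix(0, 5, 1)))))
})

test_that("PC-nonp reduces to the uncorrected test as h -> Inf", {
  set.seed(15)
  n <- 40
  P <- matrix(runif(n * 2), n, 2)
  y <- rnorm(n)
  x <- rbinom(n, 2, 0.3)
  r_np <- pc_nonp_test(y, x, pc_from_matrix(P), h = 1e7)
  r_un <- uncorrected_test(y, x)
  expect_equal(r_np$statistic, r_un$statistic, tolerance = 1e-6)
})

test_that("PC-nonp flags candidates constant after adjustment", {
  P <- matrix(runif(20), 20, 1)
  r <- pc_nonp_test(rnorm(20), rep(2, 20), pc_from_matrix(P), h = 0.5)
  expect_true(r$untestable)
})
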