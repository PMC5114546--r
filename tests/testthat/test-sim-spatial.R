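test_that("sample placement stays on the grid and supports one-per-square", {
  set.seed(201)
  cfg <- grid_config(K0 = 5, n = 2000)
  phi <- place_samples(cfg)
  expect_true(all(phi$l %in% 1:5 & phi$j %in% 1:5))
  expect_equal(phi$deme, (phi$l - 1) * 5 + phi$j - 1)
  counts <- tabulate(phi$deme + 1, 25)
  expect_lt(max(abs(counts - 80)), 5 * sqrt(80))
  cfg1 <- grid_config(K0 = 4, n = 16, placement = "one_per_square")
  phi1 <- place_samples(cfg1)
  expect_equal(sort(phi1$deme), 0:15)
  expect_error(place_samples(grid_config(K0 = 4, n = 10,
                                         placement = "one_per_square")),
               "K0\\^2")
})

test_that("genealogies are binary, ultrametric, with increasing node times", {
  set.seed(203)
  for (trial in 1:5) {
    tr <- simulate_genealogy(sample(0:8, 6, replace = TRUE), K0 = 3, M = 0.5)
    n_nodes <- length(tr$parent)
    expect_equal(n_nodes, 2 * tr$n_leaves - 1)
    expect_equal(sum(is.na(tr$parent)), 1)             # single root
    expect_true(all(tr$time[1:tr$n_leaves] == 0))      # leaves at present
    internal <- (tr$n_leaves + 1):n_nodes
    expect_true(all(diff(tr$time[internal]) > 0))      # event order
    kids <- tabulate(tr$parent[!is.na(tr$parent)], n_nodes)
    expect_true(all(kids[internal] == 2))              # binary merges
    # child precedes parent
    expect_true(all(tr$time[tr$parent[!is.na(tr$parent)]] >
                      tr$time[-which(is.na(tr$parent))] - 1e-12))
  }
})

test_that("single-deme genealogies match the Kingman E[T_MRCA]", {
  set.seed(207)
  n_lin <- 20                         # 10 diploids
  tm <- replicate(3000, tmrca(simulate_genealogy(rep(0, 10), K0 = 1, M = 1)))
  expected <- 2 * (1 - 1 / n_lin)
  expect_lt(abs(mean(tm) - expected) / expected, 0.05)
})

test_that("low migration across the grid inflates coalescence times", {
  set.seed(211)
  corner <- c(0L, 99L)                # opposite corners of a 10 x 10 grid
  t_struct <- replicate(60, tmrca(simulate_genealogy(corner, K0 = 10,
                                                     M = 0.001)))
  # a panmictic pair coalesces in 1 unit on average
  expect_gt(median(t_struct), 5)
})

test_that("mutations follow branch lengths: terminal branch, SFS law", {
  set.seed(213)
  tr <- simulate_genealogy(rep(0, 4), K0 = 1, M = 1)
  # force a terminal-branch mutation by rejection: singleton = one het
  repeat {
    mut <- drop_mutation(tr)
    if (sum(mut$genotypes) == 1) break
  }
  expect_equal(sort(unique(mut$genotypes)), c(0L, 1L))
  expect_equal(mut$maf, 1 / 8)
  # neutral panmictic site-frequency spectrum ~ 1/i
  counts <- rcpp_sfs_counts(16, 6000, theta = 0.3)
  obs <- tabulate(counts, 15)
  expect_gt(chisq.test(obs, p = (1 / 1:15) / sum(1 / 1:15))$p.value, 0.01)
})

test_that("MAF windows are honored and infeasible windows rejected", {
  set.seed(217)
  cfg <- grid_config(K0 = 3, M = 0.5, n = 40, L = 10)
  phi <- place_samples(cfg)
  g <- sim_spatial_variants(phi, cfg, 30, maf_window = c(0.05, 0.5))
  expect_true(all(g$maf >= 0.05 & g$maf <= 0.5))
  expect_error(sim_spatial_variants(phi, cfg, 1, maf_window = c(0, 0.005)),
               "1/\\(2n\\)")
  tr <- simulate_genealogy(phi$deme, cfg$K0, cfg$M)
  expect_error(drop_mutation(tr, maf_window = c(0.1, 0.2)), "tree_fn")
})

test_that("risk surfaces match their definitions", {
  s0 <- risk_surface(0, 20)
  expect_equal(sum(s0$R), 0)
  s1 <- risk_surface(1, 20)
  expect_equal(sum(s1$R == 1), 48)                  # three disjoint 4x4 blocks
  expect_equal(sum(s1$R), 48)
  expect_equal(unname(s1$R[6, 6]), 1)
  expect_equal(unname(s1$R[17, 9]), 1)              # block anchored at (14, 6)
  expect_equal(unname(s1$R[5, 5]), 0)
  s2 <- risk_surface(2, 20)
  expect_equal(unname(s2$R[6, 6]), 1)
  d1 <- s2$R[6, 8]; d2 <- s2$R[6, 12]               # farther -> smaller
  expect_gt(d1, d2)
  expect_error(risk_surface(7, 20), "unknown")
})

test_that("spatial null traits shift by beta inside risk regions", {
  set.seed(223)
  cfg <- grid_config(K0 = 20, n = 20000, risk_model = 1, beta_risk = 2)
  phi <- place_samples(cfg)
  s <- risk_surface(1, 20)
  y <- null_trait_spatial(phi, s, beta = 2)
  inside <- s$R[cbind(phi$l, phi$j)] == 1
  expect_lt(abs((mean(y[inside]) - mean(y[!inside])) - 2), 0.1)
  expect_lt(abs(var(y[!inside]) - 1), 0.05)
  # model 0 is ancestry-free standard normal
  y0 <- null_trait_spatial(phi, risk_surface(0, 20), beta = 2)
  expect_lt(abs(mean(y0)), 3 / sqrt(20000))
})

test_that("rare variants cluster in space more than common variants", {
  set.seed(227)
  cfg <- grid_config(K0 = 10, M = 0.01, n = 200)
  phi <- place_samples(cfg)
  g_rare <- sim_spatial_variants(phi, cfg, 120, maf_window = c(0.001, 0.01))
  g_comm <- sim_spatial_variants(phi, cfg, 120, maf_window = c(0.05, 0.5))
  carrier_spread <- function(G) {
    vapply(seq_len(ncol(G$values)), function(j) {
      idx <- which(G$values[, j] > 0)
      if (length(idx) < 2) return(NA_real_)
      d <- dist(cbind(phi$l[idx], phi$j[idx]))
      mean(d)
    }, 0)
  }
  sp_r <- carrier_spread(g_rare)
  sp_c <- carrier_spread(g_comm)
  expect_lt(mean(sp_r, na.rm = TRUE), mean(sp_c, na.rm = TRUE))
})

test_that("spatial cohorts assemble consistently", {
  set.seed(229)
  cfg <- grid_config(K0 = 4, M = 0.5, n = 30, L = 20, n_T = 6,
                     marker_maf = c(0.05, 0.5), candidate_maf = c(0.01, 0.2))
  co <- simulate_spatial(cfg)
  expect_equal(dim(co$markers$values), c(30L, 20L))
  expect_equal(dim(co$region$values), c(30L, 6L))
  expect_length(co$trait, 30)
  expect_equal(length(co$causal_ids), 3)
  expect_true(all(co$markers$maf >= 0.05))
  expect_true(all(co$region$maf <= 0.2))
})
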