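#' Experiment configuration
#'
#' Describes one calibration or power experiment: the cohort scenario,
#' which tests to run, single-variant or regional mode, trait type,
#' nominal levels, and the replicate/batch structure. Replicates are
#' grouped into batches; each batch generates a fresh cohort (markers,
#' PCs, h*) and every replicate within it draws a fresh trait and a
#' fresh candidate variant or region on that background, so both
#' Monte-Carlo and cohort-level variability are averaged over.
#'
#' @param scenario `"subpop"` or `"spatial"`.
#' @param scen_cfg a [subpop_config()] or [grid_config()].
#' @param tests subset of `c("Uncorrected", "GC", "PC-linear", "PC-nonp")`.
#' @param mode `"single_variant"` or `"regional"`.
#' @param trait_type `"quantitative"` or `"qualitative"` (liability
#'   threshold at mean + 1 SD).
#' @param alphas nominal levels evaluated on the same p-values.
#' @param replicates total replicates across batches.
#' @param batches number of cohort refreshes.
#' @param k number of ancestry PCs.
#' @param grid bandwidth grid (default [bandwidth_grid()] with `k`).
#' @param kol_subsample evaluate Kol(h) on this many uniformly
#'   subsampled markers during bandwidth selection (NULL = all); the PCs
#'   always use the full marker set.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scenario, scen_cfg,
                              tests = c("Uncorrected", "GC", "PC-linear",
                                        "PC-nonp"),
                              mode = c("single_variant", "regional"),
                              trait_type = c("quantitative", "qualitative"),
                              alphas = c(0.01, 0.001), replicates = 10000,
                              batches = 10, k = 10, grid = NULL,
                              kol_subsample = NULL) {
  mode <- match.arg(mode)
  trait_type <- match.arg(trait_type)
  stopifnot(scenario %in% c("subpop", "spatial"), replicates >= 1,
            all(alphas > 0 & alphas < 1), batches >= 1)
  if (is.null(grid)) grid <- bandwidth_grid(k = k)
  structure(list(scenario = scenario, scen_cfg = scen_cfg, tests = tests,
                 mode = mode, trait_type = trait_type, alphas = alphas,
                 replicates = replicates, batches = batches, k = k,
                 grid = grid, kol_subsample = kol_subsample),
            class = "experiment_config")
}

#' Two-standard-deviation binomial band for an empirical rejection rate
#'
#' alpha +/- 2 sqrt(alpha (1 - alpha) / replicates), clipped to [0, 1]
#' and rounded to two decimal places beyond the printing precision of
#' alpha. With 10,000 replicates this gives (0.008, 0.012) at alpha =
#' 0.01 and (0.00037, 0.00163) at alpha = 0.001.
#'
#' @param alpha nominal level in (0, 1).
#' @param replicates number of null replicates.
#' @return numeric `c(lo, hi)`.
#' @export
binomial_band <- function(alpha, replicates) {
  stopifnot(alpha > 0, alpha < 1, replicates >= 1)
  half <- 2 * sqrt(alpha * (1 - alpha) / replicates)
  digits <- ceiling(-log10(alpha)) + 2
  band <- round(c(max(0, alpha - half), min(1, alpha + half)), digits)
  band
}

#' Empirical type I error of the association tests
#'
#' For each batch: simulate a cohort, compute k rescaled ancestry PCs,
#' select h* by the Kolmogorov grid search (when PC-nonp is requested),
#' then run `replicates/batches` null replicates, each with a fresh null
#' trait and a fresh candidate variant (or region of rare variants
#' collapsed by Madsen-Browning weights). Rejections at each nominal
#' level are aggregated over batches. Replicates whose candidate is
#' untestable (zero variance after adjustment) are excluded and counted.
#'
#' @param config an [experiment_config()].
#' @param seed master seed; per-batch sub-seeds are drawn from it.
#' @return data.frame of class `calibration_table`: one row per (test,
#'   alpha) with `rejections`, `replicates`, `rate`, `band_lo`,
#'   `band_hi`, `in_band`; attribute `excluded` counts untestable
#'   replicates, attribute `h_star` records the per-batch bandwidths.
#' @export
run_type1 <- function(config, seed = 1) {
  pv <- collect_pvalues(config, seed, trait_builder = NULL)
  calibration_table(pv, config)
}

#' Empirical power of the association tests
#'
#' As [run_type1()] but each replicate's trait adds equal-heritability
#' causal effects from its own candidate region to the null trait, for
#' every value of `h2_grid`. Power is the rejection fraction at each
#' nominal level.
#'
#' @param config an [experiment_config()] with `mode = "regional"`.
#' @param h2_grid total region heritabilities to evaluate.
#' @param seed master seed.
#' @return data.frame: one row per (test, alpha, h2) with `power` and
#'   the replicate count.
#' @export
run_power <- function(config, h2_grid, seed = 1) {
  if (config$mode != "regional") stop("power experiments use regional mode")
  out <- NULL
  for (h2 in h2_grid) {
    pv <- collect_pvalues(config, seed, trait_builder = h2)
    for (test in names(pv$pvals)) {
      p <- pv$pvals[[test]]
      for (alpha in config$alphas) {
        out <- rbind(out, data.frame(
          test = test, alpha = alpha, h2 = h2,
          replicates = length(p), power = mean(p < alpha)))
      }
    }
  }
  out
}

# Shared replicate engine. trait_builder = NULL gives null traits (type I
# error); a numeric h2 adds causal effects from each replicate's region.
collect_pvalues <- function(config, seed, trait_builder = NULL) {
  set.seed(seed)
  batch_seeds <- sample.int(.Machine$integer.max - 1, config$batches)
  per_batch <- ceiling(config$replicates / config$batches)
  pvals <- stats::setNames(vector("list", length(config$tests)), config$tests)
  excluded <- 0
  h_stars <- numeric(0)
  for (b in seq_len(config$batches)) {
    set.seed(batch_seeds[b])
    res <- run_batch(config, per_batch, trait_builder)
    excluded <- excluded + res$excluded
    h_stars <- c(h_stars, res$h_star)
    for (test in config$tests) pvals[[test]] <- c(pvals[[test]], res$pvals[[test]])
  }
  list(pvals = pvals, excluded = excluded, h_star = h_stars)
}

run_batch <- function(config, n_rep, trait_builder) {
  cohort <- switch(config$scenario,
                   subpop = simulate_subpop(config$scen_cfg),
                   spatial = simulate_spatial(config$scen_cfg))
  markers <- cohort$markers
  n <- nrow(markers$values)

  need_pcs <- any(c("PC-linear", "PC-nonp") %in% config$tests)
  need_gc <- "GC" %in% config$tests
  pcs <- if (need_pcs) ancestry_pcs(markers, config$k) else NULL
  h_star <- NULL
  sm <- NULL
  if ("PC-nonp" %in% config$tests) {
    sel_trait <- if (config$trait_type == "qualitative")
      dichotomize(cohort$trait) else cohort$trait
    sel <- select_bandwidth(sel_trait, markers, pcs, grid = config$grid,
                            subsample = config$kol_subsample)
    h_star <- sel$h_star
    sm <- nw_smoother(pcs, h_star)
  }

  # fresh candidates: an n x n_rep matrix of scores (single variants, or
  # Madsen-Browning collapsed regions), plus region metadata for power
  cand <- make_candidates(config, cohort, n_rep)
  Y <- make_traits(config, cohort, n_rep, cand, trait_builder)

  pv <- list()
  Yc <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(cand$X, 2, colMeans(cand$X))
  stat_unc <- score_stat_cols(Yc, Xc)
  if ("Uncorrected" %in% config$tests) {
    pv[["Uncorrected"]] <- stats::pchisq(stat_unc$stat, 1, lower.tail = FALSE)
  }
  if (need_gc) {
    # per-replicate genome scan: uncorrected statistics at all markers
    Mc <- sweep(markers$values, 2, colMeans(markers$values))
    msq <- colSums(Mc^2)
    keep <- msq > 0
    U <- crossprod(Yc, Mc[, keep, drop = FALSE])        # n_rep x L
    Tm <- U^2 / outer(colSums(Yc^2), msq[keep]) * n
    lambda <- pmax(1, apply(Tm, 1, stats::median) / 0.456)
    pv[["GC"]] <- stats::pchisq(stat_unc$stat / lambda, 1, lower.tail = FALSE)
  }
  if ("PC-linear" %in% config$tests) {
    Q <- pc_projection_basis(pcs$coords)
    Yl <- Y - Q %*% crossprod(Q, Y)
    Xl <- cand$X - Q %*% crossprod(Q, cand$X)
    st <- score_stat_cols(Yl, Xl)
    pv[["PC-linear"]] <- stats::pchisq(st$stat, 1, lower.tail = FALSE)
  }
  if ("PC-nonp" %in% config$tests) {
    Yn <- residualize_sm(Y, sm)
    Xn <- residualize_sm(cand$X, sm)
    st <- score_stat_cols(Yn, Xn)
    pv[["PC-nonp"]] <- stats::pchisq(st$stat, 1, lower.tail = FALSE)
  }

  # drop replicates untestable under any requested test
  bad <- !stat_unc$testable
  pv <- lapply(pv, function(p) p[!bad])
  list(pvals = pv, excluded = sum(bad), h_star = h_star)
}

# Columnwise score statistics; V = 0 columns flagged untestable.
score_stat_cols <- function(Y, X) {
  n <- nrow(Y)
  U <- colSums(Y * X)
  V <- colSums(Y^2) * colSums(X^2) / n
  testable <- V > 0
  stat <- ifelse(testable, U^2 / pmax(V, .Machine$double.xmin), 0)
  list(stat = stat, testable = testable)
}

make_candidates <- function(config, cohort, n_rep) {
  scfg <- config$scen_cfg
  if (config$mode == "single_variant") {
    G <- fresh_variants(config, cohort, n_rep)
    list(X = G, regions = NULL, maf = colMeans(G) / 2)
  } else {
    n_T <- scfg$n_T
    G <- fresh_variants(config, cohort, n_rep * n_T)
    n <- nrow(G)
    q <- (colSums(G) + 1) / (2 * n + 2)
    w <- 1 / sqrt(n * q * (1 - q))
    X <- matrix(0, n, n_rep)
    for (r in seq_len(n_rep)) {
      idx <- ((r - 1) * n_T + 1):(r * n_T)
      X[, r] <- G[, idx, drop = FALSE] %*% w[idx]
    }
    list(X = X, regions = G, n_T = n_T, maf = colMeans(G) / 2)
  }
}

fresh_variants <- function(config, cohort, m) {
  scfg <- config$scen_cfg
  if (config$scenario == "subpop") {
    p <- sample_ancestral_maf(m)
    f <- bn_freq_matrix(p, scfg$fst, scfg$k0, 1 / (4 * scfg$n_per_subpop))
    genotypes_from_freq_matrix(f, cohort$labels)
  } else {
    rcpp_sim_genotypes(cohort$labels$deme, scfg$K0, scfg$M, m,
                       scfg$candidate_maf[1], scfg$candidate_maf[2], 100000L)
  }
}

make_traits <- function(config, cohort, n_rep, cand, trait_builder) {
  scfg <- config$scen_cfg
  n <- length(cohort$trait)
  noise <- matrix(stats::rnorm(n * n_rep), n, n_rep)
  base <- if (config$scenario == "subpop") {
    subpop_means(scfg$k0, scfg$mu)[cohort$labels]
  } else {
    scfg$beta_risk * cohort$surface$R[cbind(cohort$labels$l, cohort$labels$j)]
  }
  Y <- noise + base
  if (!is.null(trait_builder)) {  # power model: per-replicate causal effects
    h2 <- trait_builder
    n_c <- scfg$n_c
    for (r in seq_len(n_rep)) {
      idx <- ((r - 1) * cand$n_T + 1):(r * cand$n_T)
      causal <- idx[sort(sample.int(cand$n_T, n_c))]
      q <- pmax(cand$maf[causal], 1 / (2 * n))
      beta <- sqrt((h2 / n_c) / (2 * q * (1 - q)))
      Y[, r] <- Y[, r] + cand$regions[, causal, drop = FALSE] %*% beta
    }
  }
  if (config$trait_type == "qualitative") {
    cm <- colMeans(Y)
    csd <- sqrt((colSums(Y^2) - n * cm^2) / (n - 1))
    Y <- (Y >= rep(cm + csd, each = n)) + 0
  }
  Y
}

calibration_table <- function(pv, config) {
  out <- NULL
  for (test in names(pv$pvals)) {
    p <- pv$pvals[[test]]
    for (alpha in config$alphas) {
      band <- binomial_band(alpha, length(p))
      rej <- sum(p < alpha)
      out <- rbind(out, data.frame(
        test = test, alpha = alpha, rejections = rej,
        replicates = length(p), rate = rej / length(p),
        band_lo = band[1], band_hi = band[2],
        in_band = rej / length(p) >= band[1] & rej / length(p) <= band[2]))
    }
  }
  attr(out, "excluded") <- pv$excluded
  attr(out, "h_star") <- pv$h_star
  class(out) <- c("calibration_table", class(out))
  out
}

#' Quantile-quantile data for p-value uniformity
#'
#' Pairs the observed order statistics of the p-values, on the
#' -log10 scale, with the uniform expectation -log10((i - 0.5) / L).
#' Zero p-values are clamped to the smallest positive double with a
#' warning.
#'
#' @param pvals p-value vector.
#' @return data.frame with columns `expected` and `observed`, both
#'   -log10 scaled, sorted from most to least significant.
#' @export
qq_data <- function(pvals) {
  L <- length(pvals)
  if (L == 0) stop("empty p-value vector")
  if (any(pvals == 0)) {
    warning("zero p-values clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  data.frame(expected = -log10((seq_len(L) - 0.5) / L),
             observed = -log10(sort(pvals)))
}
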