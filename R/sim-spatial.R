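#' Configuration for the spatial-grid simulator
#'
#' Parameters of simulation set 2: a K0 x K0 grid of demes with
#' population-scaled migration rate M, genotypes generated by a
#' structured coalescent (one independent genealogy per variant, no
#' recombination), and a nongenetic spatial risk surface added to the
#' trait with coefficient beta.
#'
#' @param K0 grid side (default 20).
#' @param M population-scaled migration rate (default 0.01).
#' @param n diploid sample size.
#' @param placement `"uniform"` (each individual's origin square drawn
#'   uniformly) or `"one_per_square"` (requires n = K0^2).
#' @param risk_model 0 (flat), 1 (three sharp 4x4 unit blocks) or 2
#'   (wide Gaussian bump).
#' @param beta_risk risk coefficient (default 2).
#' @param L background markers; `marker_maf` their folded-MAF window
#'   (common variants by default, which carry the ancestry signal).
#' @param n_T,n_c,h2 candidate-region size, causal count, total
#'   heritability; `candidate_maf` the region's folded-MAF window (rare
#'   variants by default).
#' @return list of class `grid_config`.
#' @export
grid_config <- function(K0 = 20, M = 0.01, n = 500, placement = "uniform",
                        risk_model = 0, beta_risk = 2, L = 10000,
                        marker_maf = c(0.01, 0.5), n_T = 10,
                        n_c = n_T %/% 2, candidate_maf = c(0.001, 0.01),
                        h2 = 0.01) {
  stopifnot(K0 >= 2, M > 0, n >= 2, risk_model %in% 0:2)
  structure(list(K0 = K0, M = M, n = n, placement = placement,
                 risk_model = risk_model, beta_risk = beta_risk, L = L,
                 marker_maf = marker_maf, n_T = n_T, n_c = n_c,
                 candidate_maf = candidate_maf, h2 = h2),
            class = "grid_config")
}

#' Assign individuals to grid squares of origin
#'
#' Returns the map phi from individuals to 1-based grid coordinates
#' (l, j); each diploid individual contributes two haploid lineages
#' starting in its square.
#'
#' @param cfg a [grid_config()].
#' @return data.frame with columns `l`, `j` (1..K0) and `deme`
#'   (0-based row-major index used internally).
#' @export
place_samples <- function(cfg) {
  D <- cfg$K0^2
  deme <- switch(cfg$placement,
    uniform = sample.int(D, cfg$n, replace = TRUE) - 1L,
    one_per_square = {
      if (cfg$n != D) stop("one_per_square placement requires n = K0^2")
      sample.int(D) - 1L
    },
    stop("unknown placement rule: ", cfg$placement)
  )
  data.frame(l = deme %/% cfg$K0 + 1L, j = deme %% cfg$K0 + 1L, deme = deme)
}

#' Simulate one genealogy under the structured coalescent
#'
#' Backward-in-time simulation on the migration grid: within-deme
#' coalescence at rate 1 per lineage pair, migration of each lineage at
#' total rate M/2 split equally among rook-adjacent squares with
#' reflecting boundaries. Each diploid individual contributes two
#' colocated lineages. With K0 = 1 this is the standard Kingman
#' coalescent.
#'
#' @param phi sample placement from [place_samples()] (its `deme`
#'   column), or directly an integer vector of 0-based deme indices per
#'   individual.
#' @param K0 grid side.
#' @param M population-scaled migration rate.
#' @return list of class `genealogy`: `parent` (1-based parent pointer
#'   per node, NA at the root), `time` (node times in coalescent units,
#'   leaves at 0), `n_leaves`. Leaves 2i - 1 and 2i belong to individual
#'   i.
#' @export
simulate_genealogy <- function(phi, K0, M) {
  deme <- if (is.data.frame(phi)) phi$deme else as.integer(phi)
  stopifnot(all(deme >= 0), all(deme < K0^2))
  lin <- rep(deme, each = 2)
  tr <- rcpp_simulate_genealogy(lin, K0, M)
  parent <- tr$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = tr$time, n_leaves = tr$n_leaves),
            class = "genealogy")
}

#' Time to the most recent common ancestor
#'
#' @param tree a `genealogy`.
#' @return the root node time, in coalescent units.
#' @export
tmrca <- function(tree) tree$time[which(is.na(tree$parent))]

#' Drop a single mutation on a genealogy
#'
#' Infinite-sites mutation: a branch is chosen with probability
#' proportional to its length and all leaves below it carry the derived
#' allele; the diploid genotype is the number of carrier lineages among
#' an individual's two leaves. If `maf_window` is given and the folded
#' sample MAF falls outside it, a fresh genealogy is requested from
#' `tree_fn` and the mutation redrawn (tree and mutation are rejected
#' together).
#'
#' @param tree a `genealogy`.
#' @param maf_window optional `c(lo, hi)` folded-MAF acceptance window.
#' @param tree_fn zero-argument function returning a fresh `genealogy`;
#'   required when `maf_window` is given (defaults to resampling being
#'   disabled: a single attempt whose MAF may fall anywhere).
#' @param max_tries rejection cap.
#' @return list: `genotypes` (derived-allele count per individual),
#'   `maf` (folded sample frequency), `node` (mutated branch's child
#'   node), `tree` (the accepted genealogy).
#' @export
drop_mutation <- function(tree, maf_window = NULL, tree_fn = NULL,
                          max_tries = 1000) {
  nl <- tree$n_leaves
  if (!is.null(maf_window)) {
    if (maf_window[2] < 1 / nl) {
      stop("maf window upper bound below 1/(2n); infeasible for this sample size")
    }
    if (is.null(tree_fn)) stop("maf_window requires a tree_fn to redraw genealogies")
  }
  for (try in seq_len(max_tries)) {
    lens <- tree$time[tree$parent] - tree$time  # NA at root
    v <- sample.int(length(lens), 1, prob = ifelse(is.na(lens), 0, lens))
    carrier <- subtree_leaves(tree, v)
    count <- sum(carrier)
    maf <- min(count, nl - count) / nl
    ok <- if (is.null(maf_window)) TRUE else
      (maf >= maf_window[1] && maf <= maf_window[2])
    if (ok) {
      g <- carrier[seq(1, nl, by = 2)] + carrier[seq(2, nl, by = 2)]
      if (count > nl - count) g <- 2L - g
      return(list(genotypes = as.integer(g), maf = maf, node = v, tree = tree))
    }
    tree <- tree_fn()
  }
  stop("maf window not met after ", max_tries, " genealogies")
}

# 0/1 indicator over leaves of membership in the subtree rooted at v.
subtree_leaves <- function(tree, v) {
  n_nodes <- length(tree$parent)
  below <- logical(n_nodes)
  below[v] <- TRUE
  # parents always have larger indices than their children were created
  # after them, so one downward sweep suffices
  for (u in seq(n_nodes, 1)) {
    if (!below[u] && !is.na(tree$parent[u]) && below[tree$parent[u]]) {
      below[u] <- TRUE
    }
  }
  as.integer(below[seq_len(tree$n_leaves)])
}

#' Nongenetic spatial risk surface
#'
#' Model 0: no stratification, R = 0 everywhere. Model 1: small, sharp
#' risk -- three disjoint 4x4 unit blocks with lower corners at (6, 6),
#' (14, 6) and (14, 14); R = 1 inside, 0 outside. Model 2: wide, smooth
#' risk -- a Gaussian bump centered at (6, 6),
#' R = exp(-((l - 6)^2 + (j - 6)^2) / (2 sigma^2)), sigma = 5 by
#' default (about a quarter of the default grid).
#'
#' @param model 0, 1 or 2.
#' @param K0 grid side.
#' @param sigma width of the model-2 bump.
#' @param anchors model-1 block corners as a 2-column matrix (rows are
#'   (l0, j0)).
#' @return list of class `risk_surface`: `R` (K0 x K0 matrix, row l,
#'   column j, 1-based grid coordinates) and `model`.
#' @export
risk_surface <- function(model, K0 = 20, sigma = 5,
                         anchors = rbind(c(6, 6), c(14, 6), c(14, 14))) {
  if (!model %in% 0:2) stop("unknown risk model: ", model)
  R <- matrix(0, K0, K0)
  if (model == 1) {
    for (r in seq_len(nrow(anchors))) {
      l0 <- anchors[r, 1]; j0 <- anchors[r, 2]
      ls <- intersect(l0:(l0 + 3), seq_len(K0))
      js <- intersect(j0:(j0 + 3), seq_len(K0))
      R[ls, js] <- 1
    }
  } else if (model == 2) {
    l <- matrix(seq_len(K0), K0, K0)
    j <- t(l)
    R <- exp(-((l - 6)^2 + (j - 6)^2) / (2 * sigma^2))
  }
  structure(list(R = R, model = model), class = "risk_surface")
}

#' Null trait over the spatial risk surface
#'
#' y_i = beta * R at individual i's origin square + standard normal
#' noise; independent of all genotypes.
#'
#' @param phi placement data.frame from [place_samples()].
#' @param surface a [risk_surface()].
#' @param beta risk coefficient.
#' @return numeric trait vector.
#' @export
null_trait_spatial <- function(phi, surface, beta = 2) {
  beta * surface$R[cbind(phi$l, phi$j)] + stats::rnorm(nrow(phi))
}

#' Batch variant simulation on the migration grid
#'
#' Simulates `m` variants, each on its own independent genealogy, with an
#' optional folded-MAF acceptance window (tree and mutation redrawn
#' together on rejection).
#'
#' @param phi placement from [place_samples()].
#' @param cfg a [grid_config()].
#' @param m number of variants.
#' @param maf_window folded-MAF window `c(lo, hi)`, or NULL for any
#'   polymorphic variant.
#' @param max_tries per-variant rejection cap.
#' @return a [genotype_matrix()] (n x m minor-allele counts).
#' @export
sim_spatial_variants <- function(phi, cfg, m, maf_window = NULL,
                                 max_tries = 10000) {
  win <- if (is.null(maf_window)) c(0, 0.5) else maf_window
  G <- rcpp_sim_genotypes(phi$deme, cfg$K0, cfg$M, m, win[1], win[2],
                          max_tries)
  genotype_matrix(G)
}

#' Simulate a spatially structured cohort
#'
#' Generates background markers (common variants) and a candidate region
#' (rare variants) on independent genealogies, origin squares, the risk
#' surface, and a null trait.
#'
#' @param cfg a [grid_config()].
#' @return list of class `sim_cohort` with fields `markers`, `region`,
#'   `trait`, `labels` (the placement data.frame), `surface`,
#'   `causal_ids` and `truth`.
#' @export
simulate_spatial <- function(cfg) {
  stopifnot(inherits(cfg, "grid_config"))
  phi <- place_samples(cfg)
  surface <- risk_surface(cfg$risk_model, cfg$K0)
  markers <- sim_spatial_variants(phi, cfg, cfg$L, cfg$marker_maf)
  region <- sim_spatial_variants(phi, cfg, cfg$n_T, cfg$candidate_maf)
  causal_ids <- sort(sample.int(cfg$n_T, cfg$n_c))
  trait <- null_trait_spatial(phi, surface, cfg$beta_risk)
  structure(
    list(markers = markers, region = region, trait = trait, labels = phi,
         surface = surface, causal_ids = causal_ids,
         truth = list(config = cfg)),
    class = "sim_cohort"
  )
}

#' Add regional causal effects to a spatial null trait
#'
#' Identical equal-heritability construction as [power_trait()], applied
#' on top of the spatial null trait.
#'
#' @inheritParams power_trait
#' @return numeric trait vector under the alternative.
#' @export
power_trait_spatial <- function(region, causal_ids, h2, null_trait,
                                maf = NULL) {
  power_trait(region, causal_ids, h2, null_trait, maf)
}
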