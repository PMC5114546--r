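#' Configuration for the discrete-subpopulation simulator
#'
#' Collects the parameters of simulation set 1: k0 Balding-Nichols
#' subpopulations at a given F_st, background markers for ancestry
#' inference, and a candidate region of n_T variants of which
#' n_c = n_T / 2 are causal under the power model. The subpopulation
#' trait-mean scale mu defaults to 5 when k0 = 20 and to 2 otherwise.
#'
#' @param k0 number of subpopulations (k0 = 1 is a homogeneous cohort).
#' @param fst Wright's fixation index, in (0, 1); default 0.01.
#' @param n_per_subpop diploid samples per subpopulation.
#' @param L number of background genomic markers.
#' @param n_T number of candidate-region variants.
#' @param n_c number of causal variants (default n_T / 2).
#' @param mu subpopulation mean scale.
#' @param h2 total trait heritability of the region under the power model.
#' @return list of class `subpop_config`.
#' @export
subpop_config <- function(k0 = 1, fst = 0.01, n_per_subpop = 1000 %/% k0,
                          L = 10000, n_T = 10, n_c = n_T %/% 2,
                          mu = if (k0 == 20) 5 else 2, h2 = 0.01) {
  stopifnot(k0 >= 1, fst > 0, fst < 1, n_per_subpop >= 1, n_c <= n_T)
  structure(list(k0 = k0, fst = fst, n_per_subpop = n_per_subpop, L = L,
                 n_T = n_T, n_c = n_c, mu = mu, h2 = h2),
            class = "subpop_config")
}

#' Draw ancestral minor-allele frequencies
#'
#' Emulates an exome-like MAF spectrum: with probability 0.6 a rare
#' frequency uniform on (0.0005, 0.01), otherwise a common frequency
#' uniform on (0.01, 0.5). This built-in spectrum is a synthetic
#' surrogate for an empirical exome frequency table; pass `spectrum` (a
#' numeric vector of frequencies, e.g. read from a file) to resample an
#' empirical spectrum instead.
#'
#' @param n_draws number of frequencies to draw.
#' @param spectrum optional numeric vector of frequencies in (0, 0.5] to
#'   resample with replacement.
#' @return numeric vector of ancestral MAFs in (0, 0.5].
#' @export
sample_ancestral_maf <- function(n_draws, spectrum = NULL) {
  if (!is.null(spectrum)) {
    if (length(spectrum) == 0) stop("empty MAF spectrum")
    if (any(spectrum <= 0 | spectrum > 0.5)) {
      stop("spectrum frequencies must lie in (0, 0.5]")
    }
    return(sample(spectrum, n_draws, replace = TRUE))
  }
  rare <- stats::runif(n_draws) < 0.6
  ifelse(rare,
         stats::runif(n_draws, 0.0005, 0.01),
         stats::runif(n_draws, 0.01, 0.5))
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws k0 independent subpopulation frequencies from
#' Beta(p (1 - F_st)/F_st, (1 - p)(1 - F_st)/F_st), whose mean is the
#' ancestral frequency p and whose variance is p (1 - p) F_st. Draws are
#' rejected and redrawn until the variant is expected to be polymorphic
#' in the pooled sample: at least one subpopulation frequency must reach
#' `min_freq` (by default 1/(4 n_per_subpop), i.e. half an expected
#' allele copy in some subpopulation).
#'
#' @param p ancestral allele frequency in (0, 1).
#' @param fst fixation index in (0, 1).
#' @param k0 number of subpopulations.
#' @param min_freq acceptance threshold for the largest subpopulation
#'   frequency.
#' @return numeric vector of k0 subpopulation frequencies.
#' @export
balding_nichols_freqs <- function(p, fst, k0, min_freq = 0) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  repeat {
    f <- stats::rbeta(k0, a, b)
    if (max(f) >= min_freq) return(f)
  }
}

# Vectorized variant in batch form: draws a k0 x m frequency matrix with
# per-column rejection, used by the cohort generator.
bn_freq_matrix <- function(p, fst, k0, min_freq) {
  m <- length(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  f <- matrix(stats::rbeta(k0 * m, rep(a, each = k0), rep(b, each = k0)),
              nrow = k0)
  bad <- which(apply(f, 2, max) < min_freq)
  while (length(bad) > 0) {
    f[, bad] <- stats::rbeta(k0 * length(bad), rep(a[bad], each = k0),
                             rep(b[bad], each = k0))
    bad <- bad[apply(f[, bad, drop = FALSE], 2, max) < min_freq]
  }
  f
}

#' Hardy-Weinberg genotypes from subpopulation frequencies
#'
#' Each individual in subpopulation i draws Binomial(2, freqs[i]).
#'
#' @param freqs length-k0 vector of subpopulation allele frequencies.
#' @param labels subpopulation index (1..k0) per individual.
#' @return integer genotype vector, one entry per individual.
#' @export
genotypes_from_freqs <- function(freqs, labels) {
  stats::rbinom(length(labels), 2, freqs[labels])
}

# Batch genotype generation for a whole frequency matrix (k0 x m).
genotypes_from_freq_matrix <- function(freqs, labels) {
  n <- length(labels)
  m <- ncol(freqs)
  probs <- freqs[labels, , drop = FALSE]
  matrix(stats::rbinom(n * m, 2, probs), nrow = n)
}

#' Null quantitative trait with subpopulation means
#'
#' y = mu_label + e with standard normal e, independent of all genotypes.
#' For k0 <= 2 the means are (0, mu); for k0 > 2 the subpopulations are
#' assigned means evenly spaced on [0, mu].
#'
#' @param labels subpopulation index (1..k0) per individual.
#' @param k0 number of subpopulations.
#' @param mu subpopulation mean scale.
#' @return numeric trait vector.
#' @export
null_trait_quant <- function(labels, k0, mu = if (k0 == 20) 5 else 2) {
  subpop_means(k0, mu)[labels] + stats::rnorm(length(labels))
}

subpop_means <- function(k0, mu) {
  if (k0 == 1) 0 else if (k0 == 2) c(0, mu) else mu * (seq_len(k0) - 1) / (k0 - 1)
}

#' Add equal-heritability causal effects to a null trait
#'
#' y = sum_l beta_l x_l + y0 where every causal variant contributes the
#' same heritability h2 / n_c, so rarer variants get larger effects:
#' beta_l = sqrt((h2 / n_c) / (2 q_l (1 - q_l))) with q_l the variant's
#' generating minor-allele frequency. All effects are positive by
#' default.
#'
#' @param region [genotype_matrix()] (or plain matrix) of region variants.
#' @param causal_ids column indices of the causal variants.
#' @param h2 total heritability contributed by the region, in [0, 1).
#' @param maf generating MAF per region variant (defaults to the sample
#'   MAF of `region`).
#' @param null_trait the trait vector generated under the null.
#' @return numeric trait vector under the alternative.
#' @export
power_trait <- function(region, causal_ids, h2, null_trait, maf = NULL) {
  if (h2 >= 1) stop("total heritability h2 must be < 1")
  G <- if (inherits(region, "genotype_matrix")) region$values else
    as.matrix(region)
  if (is.null(maf)) maf <- colMeans(G) / 2
  if (h2 == 0 || length(causal_ids) == 0) return(null_trait)
  q <- maf[causal_ids]
  beta <- sqrt((h2 / length(causal_ids)) / (2 * q * (1 - q)))
  drop(G[, causal_ids, drop = FALSE] %*% beta) + null_trait
}

#' Liability-threshold affection status
#'
#' An individual is affected when its quantitative trait is at least one
#' standard deviation above the cohort mean; on a normal trait this gives
#' a population prevalence of about 16%. The affected set is invariant to
#' affine transformations of the trait.
#'
#' @param y quantitative trait vector.
#' @return integer 0/1 affection vector.
#' @export
dichotomize <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("trait has zero variance; cannot threshold")
  as.integer(y >= mean(y) + s)
}

#' Simulate a discrete-subpopulation cohort
#'
#' Generates background markers and a candidate region under the
#' Balding-Nichols model, subpopulation labels, a null quantitative
#' trait, and causal-variant metadata. Markers and region variants are
#' mutually independent (no linkage disequilibrium by construction).
#'
#' @param cfg a [subpop_config()].
#' @param spectrum optional empirical MAF spectrum (see
#'   [sample_ancestral_maf()]).
#' @return list of class `sim_cohort` with fields `markers`, `region`
#'   (genotype matrices), `trait` (null quantitative trait), `labels`,
#'   `causal_ids`, and `truth` (generating frequencies and config).
#' @export
simulate_subpop <- function(cfg, spectrum = NULL) {
  stopifnot(inherits(cfg, "subpop_config"))
  n <- cfg$k0 * cfg$n_per_subpop
  labels <- rep(seq_len(cfg$k0), each = cfg$n_per_subpop)
  min_freq <- 1 / (4 * cfg$n_per_subpop)

  p_mark <- sample_ancestral_maf(cfg$L, spectrum)
  f_mark <- bn_freq_matrix(p_mark, cfg$fst, cfg$k0, min_freq)
  markers <- genotype_matrix(genotypes_from_freq_matrix(f_mark, labels))

  p_reg <- sample_ancestral_maf(cfg$n_T, spectrum)
  f_reg <- bn_freq_matrix(p_reg, cfg$fst, cfg$k0, min_freq)
  region <- genotype_matrix(genotypes_from_freq_matrix(f_reg, labels))

  causal_ids <- sort(sample.int(cfg$n_T, cfg$n_c))
  trait <- null_trait_quant(labels, cfg$k0, cfg$mu)
  structure(
    list(markers = markers, region = region, trait = trait, labels = labels,
         causal_ids = causal_ids,
         truth = list(config = cfg, marker_p = p_mark, marker_freqs = f_mark,
                      region_p = p_reg, region_freqs = f_reg)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d markers, %d region variants\n",
              length(x$trait), ncol(x$markers$values),
              ncol(x$region$values)))
  invisible(x)
}
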