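---
title: "Kernel-regression correction for population stratification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-regression correction for population stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnonp)
```

## The problem

Rare-variant association tests compare a phenotype $y$ with a genotype
score $x$ (a single variant's minor-allele count, or a weighted sum over
a region). When cases and controls differ in ancestry, both $y$ and $x$
co-vary with ancestry and spurious associations appear. The standard
remedy regresses $y$ and $x$ on the leading principal components (PCs)
of genome-wide genotypes and tests the residuals — but that only removes
*linear* dependence on the PCs. Trait means can depend on ancestry in
sharply nonlinear ways (e.g. a disease risk confined to a small
geographic pocket), and rare variants are themselves strongly localized
in ancestry space, so the linear correction can fail exactly where rare
variants need it most.

## The model

Let $p_i \in [0,1]^k$ be the first $k$ ancestry PCs of individual $i$,
each rescaled to the unit interval. Both trait and genotype score are
modeled as arbitrary smooth functions of ancestry plus noise:

$$y_i = \mu_1(p_i) + \varepsilon_i, \qquad x_i = \mu_2(p_i) + \eta_i.$$

The two regression functions are estimated by Nadaraya–Watson smoothing
with a product quartic (biweight) kernel
$K(u) = \tfrac{15}{16}(1-u^2)^2 \mathbf{1}\{|u|\le 1\}$ and one common
bandwidth $h$:

$$\hat\mu(p_i) = \frac{\sum_j W_{ij}\, v_j}{\sum_j W_{ij}}, \qquad
  W_{ij} = \prod_{d=1}^{k} K\!\left(\frac{p_{id}-p_{jd}}{h}\right).$$

The fitted value at $i$ is the kernel-weighted mean over individuals
with similar ancestry; the $1/h^k$ normalizing constant cancels in the
ratio and is omitted. The sum includes $j = i$, so the denominator is
always at least $(15/16)^k$ and isolated points are well defined; the
price is a small self-weight that makes very small bandwidths
over-adjust (residuals shrink toward zero), which the bandwidth
selection rule penalizes.

The association test is the 1-df score test on the residual pair
$\tilde y = y - \hat\mu_1(p)$, $\tilde x = x - \hat\mu_2(p)$:

$$T = \frac{U^2}{V}, \qquad U = \sum_i \tilde y_i \tilde x_i, \qquad
  V = \frac{\sum_i \tilde y_i^2 \sum_i \tilde x_i^2}{n},$$

so that on centered inputs $T = n r^2$ with $r$ the Pearson correlation,
and $T \sim \chi^2_1$ under the null. Regional tests first collapse the
region with Madsen–Browning weights
$w_m = 1/\sqrt{n \hat q_m (1-\hat q_m)}$,
$\hat q_m = (\sum_i g_{im}+1)/(2n+2)$, so rarer variants weigh more and
monomorphic columns stay finite.

## Bandwidth selection by p-value uniformity

$h$ controls everything: $h \to \infty$ recovers the uncorrected test,
$h \to 0$ over-adjusts. The selection rule exploits that the background
markers used to build the PCs are (almost all) null: for each candidate
$h$, run the single-variant test at all $L$ markers and measure the
Kolmogorov distance $\mathrm{Kol}(h)$ between the $L$ p-values and the
uniform distribution, computed exactly over order statistics as
$\max_i \max(i/L - p_{(i)},\ p_{(i)} - (i-1)/L)$. Under-adjustment
leaves an excess of small p-values, over-adjustment an excess of large
ones; $\mathrm{Kol}(h)$ is bowl-shaped in $-\log h$ and the minimizing
$h^*$ is kept for every subsequent candidate test. The grid is dyadic,
$h_s = 2^{2(s-23)/(5+k)}$ for $s = 1,\dots,30$, spanning roughly
$[0.13, 1.9]$ on the unit PC scale for $k = 10$; ties are broken toward
the larger $h$ (the milder adjustment). Each grid point costs one
$n \times n$ weight matrix and one pass over the markers, and
$\mathrm{Kol}(h)$ may be evaluated on a uniform subsample of markers —
it depends only on the p-value distribution — which is how the
packaged experiments keep 30-point searches over 10,000-marker panels
affordable.

## Comparison tests

* **Uncorrected** — the same score test on mean-centered $y$ and $x$.
* **Genomic control** — the uncorrected statistic divided by
  $\lambda = \max(1, \mathrm{median}_l T_l / 0.456)$ estimated from the
  marker statistics (0.456 is the $\chi^2_1$ median).
* **PC-linear** — least-squares residuals on an intercept plus the $k$
  PCs, then the score test; the linear special case that PC-nonp
  generalizes.

Binary (affected/unaffected) traits are passed through the same
machinery with 0/1 coding; disease status is generated by a liability
threshold at one standard deviation above the cohort mean
(≈16% prevalence on a normal liability).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | ancestry PCs used by all corrected tests (unitless coordinates rescaled to [0,1]) |
| `h` | selected | common kernel bandwidth on the [0,1] PC scale |
| grid `S` | 30 | dyadic bandwidth grid points |
| `L` | 10,000 | background markers for PCs and bandwidth calibration |
| `fst` | 0.01 | Wright's fixation index of the subpopulation simulator |
| `mu` | 2 (5 if $k_0$=20) | subpopulation trait-mean scale |
| `K0`, `M` | 20, 0.01 | migration-grid side and population-scaled migration rate |
| `beta_risk` | 2 | spatial nongenetic risk coefficient |
| `n_T`, `n_c` | 10, 5 | region size and causal count; equal per-variant heritability |

The marker panel size deserves emphasis: with 20 subpopulations at
$F_{st} = 0.01$, 10 PCs computed from only 2,000 markers recover barely
half of the subpopulation labels and no bandwidth can make the marker
p-values uniform, while 10,000 markers recover ~99% of labels and give
$\mathrm{Kol}(h^*) \approx 0.01$. The packaged experiments therefore use
10,000-marker panels for the strongly structured scenarios.

## The simulators

**Discrete subpopulations.** Ancestral MAFs are drawn from a built-in
synthetic exome-like spectrum — a 60/40 mixture of rare
($p \sim U(0.0005, 0.01)$) and common ($p \sim U(0.01, 0.5)$)
frequencies, standing in for an empirical exome frequency table (a user
spectrum can be supplied). Subpopulation frequencies follow the
Balding–Nichols model,
$\mathrm{Beta}(p(1-F_{st})/F_{st},\ (1-p)(1-F_{st})/F_{st})$, redrawn
until at least one subpopulation frequency reaches $1/(4 n_{sub})$ so
the variant is expected polymorphic; genotypes are Hardy–Weinberg
binomials. Null traits are $y = \mu_{\text{label}} + N(0,1)$ with means
$(0, \mu)$ for $k_0 \le 2$ and evenly spaced on $[0, \mu]$ otherwise
(the even spacing is this package's choice; calibration is insensitive
to the exact assignment). Power traits add
$\beta_l = \sqrt{(h^2/n_c) / (2 q_l (1-q_l))}$ per causal variant, so
every causal variant contributes equal heritability and rarer variants
get larger effects; the genetic variance added is $h^2$ in absolute
units, hence a variance *fraction* of $h^2/(1+h^2)$.

**Spatial grid.** Genotypes come from a backward-in-time structured
coalescent on a $K_0 \times K_0$ grid: within-deme coalescence at rate 1
per lineage pair, per-lineage migration at total rate $M/2$ split
equally over rook-adjacent squares with reflecting boundaries (the
simplest irreducible nearest-neighbour kernel; the calibration targets
depend on stratification being present, not on the exact kernel). Each
diploid contributes two colocated lineages; each variant gets its own
independent genealogy (no recombination or LD) and one infinite-sites
mutation on a branch chosen proportional to length, rejected and
redrawn (tree and all) until the folded sample MAF enters the requested
window — common windows (MAF 0.01–0.5) for ancestry markers, rare
windows (0.001–0.01) for candidates. Null traits add a nongenetic risk
surface: model 0 is flat, model 1 puts unit risk on three 4×4 blocks
anchored at (6,6), (14,6), (14,14), and model 2 is a wide Gaussian bump
$\exp(-((l-6)^2+(j-6)^2)/(2\sigma^2))$ with $\sigma = 5$ (the smooth
surface's exact form is this package's choice, exposed via arguments).

One numerical caveat, verified by the test suite: drawing exactly one
mutation per genealogy produces a site-frequency spectrum equal to
$E[L_i/L_{tot}]$, which differs slightly from the textbook
$1/i$ law $E[L_i]/E[L_{tot}]$; the physics checks therefore use
Poisson-on-branches mutations (where the $1/i$ law is exact), while the
genotype generator keeps the one-variant-per-tree design that makes
replicates independent.

## Replicate structure and determinism

Type-I-error and power experiments are batched: each batch simulates a
fresh cohort, computes PCs, selects $h^*$ once, and then runs many
replicates, each with a fresh null trait and a fresh candidate variant
or region on that shared background. Batching averages over cohort
realizations — the bandwidth search is itself noisy, and single-cohort
rejection rates at $k_0 = 20$ scatter noticeably around the long-run
mean — while keeping the per-replicate cost to a handful of
matrix–vector products. All randomness flows from one master seed
through per-batch sub-seeds, so identical configurations and seeds give
bit-identical tables. Replicates whose candidate is monomorphic in the
sample are excluded and counted.

## Numerical choices and degenerate inputs

* Markers are standardized by $\sqrt{q(1-q)}$ after mean-centering;
  monomorphic (zero-variance) markers are dropped with a logged count.
  PC signs are fixed by making each component's largest-magnitude entry
  positive.
* The score test reports `untestable` (statistic 0, p-value 1) when the
  adjusted genotype — or trait — vector is identically zero.
* $\mathrm{Kol}$ ties on the bandwidth grid resolve to the larger $h$.
* Zero p-values in QQ data are clamped to the smallest positive double.
* The liability threshold uses the simulated cohort's own mean and SD,
  making the affected set invariant to affine trait transformations.

## What the simulations do and do not show

The generators reproduce the calibration-relevant features of real
cohorts — ancestry-confounded trait means (smooth or sharply localized),
an exome-like rare-heavy frequency spectrum, geographic clustering of
rare variants — but not linkage disequilibrium, admixture gradients
within individuals, genotyping error, or relatedness. Passing
calibration here shows the correction handles nonlinear
ancestry–trait confounding; it does not certify behaviour under LD
between candidate and markers or under cryptic relatedness.

Known limitations worth stating plainly. First, with 0/1 traits and
ultra-rare candidates (a handful of minor-allele copies) the score
statistic's numerator is a short sum of skewed two-point terms, and its
$\chi^2_1$ tail is anti-conservative once strong stratification has
been residualized away (the product-variance $V$ shrinks with the
trait residuals while the sparse-sum tail does not); the effect is
concentrated below ~5 carriers and visible in the structured
qualitative scenario. Second, the kernel correction is only as good as
the PC panel: too few background markers leave residual stratification
that no bandwidth can remove. Third, per-dimension bandwidths,
local-linear smoothing and cross-validation rules are out of scope —
the single common $h$ with uniformity-based selection is the method.

## Problem sizes in the packaged checks

The test suite and the acceptance script run the full pipeline at desk
scale, chosen to keep the whole suite in the tens of minutes on one
core: cohorts of $n = 1000$ (subpopulations) or $n = 500$ (grid),
10,000-marker panels for structured scenarios (2,000 where structure is
absent), 1,500–3,000 null replicates per scenario spread over 4–6
cohort batches (single-cohort rejection rates scatter noticeably, so
batching matters more than raw replicate count), 400-replicate power
points, and Kol evaluated on 2,000–5,000-marker subsamples. Published reference values were computed
at 10,000 replicates, so reduced-scale estimates are compared through
the 2-SD binomial band of the replicate count actually used.
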