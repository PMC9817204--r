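---
title: "Methods: spatial phylogenetic diversity, endemism, and their drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phylogenetic diversity, endemism, and their drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscape)
```

# Scope

`phyloscape` analyses gridded communities of species bound to a rooted
phylogeny: it maps where evolutionary history is concentrated
(phylogenetic diversity, PD), where it is spatially restricted
(phylogenetic endemism, PE; weighted endemism, WE), asks whether those
concentrations exceed what random phylogenetic structure would produce
(permutation nulls), and models their environmental and topographic
drivers with spatial-error regressions selected by AIC. A synthetic-data
generator with known ground truth exercises the whole chain, which is how
the package validates itself: real regional atlas datasets of this kind
are typically not redistributable.

The motivating setting is a regional amphibian fauna — a few dozen
species on a 10 km occurrence grid of order $10^3$–$10^4$ cells — and the
generator's defaults mirror that: 27 species, a $32 \times 32$ grid, one
extreme micro-endemic.

# Diversity metrics

All three per-cell metrics are driven by one shared structure, the
*branch range table*: for every branch of the tree, the set of grid cells
occupied by at least one descendant tip. For a cell $c$ with species set
$S_c$:

* **PD** is rooted Faith diversity, the summed length of all branches on
  the union of root-to-tip paths of $S_c$. Rooted means a single-species
  cell scores that species' full root path, not zero; this follows the
  convention that diversity is measured against the root of the regional
  tree.
* **PE** divides each branch length $L_b$ by its range size $R_b$ (cells)
  before summing over the cell's branches:
  $PE(c) = \sum_{b \ni c} L_b / R_b$. Every branch's length is thereby
  apportioned exactly once across the map, so
  $\sum_c PE(c)$ equals the total branch length of the tree pruned to
  species with at least one occurrence — an identity the tests assert to
  $10^{-9}$ on 100 random systems.
* **WE** is the taxon-level analogue, $\sum_{s \in S_c} 1/R_s$, and sums
  to the species count.

Empty cells are kept in the tables with zeros but never modelled.
Micro-endemics (default: range below 3 cells) can be removed before
modelling with `filter_restricted_species()`; a species confined to one
or two cells injects extreme PE scores there that destabilize regression
fits, which is why the filter exists.

# Null models

Two randomizations are provided.

**Tip shuffle** permutes species across tree tips, holding topology,
branch lengths, and the community matrix fixed. Under it, a cell's null
PD distribution depends only on its richness. **Independent swap** is the
fixed–fixed community randomization: random $2\times2$ checkerboard
submatrices are flipped, preserving species range sizes and cell richness
exactly at every step; the default effort is 10 attempted swaps per
presence.

One randomization is shared by all cells per replicate (whole-map
randomization), 999 replicates by default. Per cell we report the null
mean and SD, $SES = (obs - \overline{null})/sd(null)$, and a rank
p-value that pools the observed value with the replicates and
half-counts ties:

$$p = \frac{\#\{null < obs\} + \tfrac12\#\{null = obs\} + \tfrac12}{n_{reps}+1}.$$

This convention is chosen so that a cell whose metric is invariant under
the null (a cell holding every species, or any cell on a star tree with
equal branches) lands at exactly $p = 0.5$; its attainable range is
$[0.5/(n+1),\ (n+0.5)/(n+1)]$. Such cells have null SD 0 and are flagged
`degenerate`, with SES reported as 0 rather than NaN so the null mean
remains usable as a model covariate. Ties are detected at a relative
tolerance of $10^{-9}$. Significance (`classify_significant()`) is the
one-sided high tail, strictly $p > 0.95$ by default.

# Predictors

**Terrain.** From a DEM on the rectangular grid, an 8-neighbor window
yields TPI (cell minus neighbor mean) and TRI (mean absolute neighbor
difference); slope comes from Horn's $3\times3$ finite differences, in
degrees. Edge cells use the neighbors that exist; the Horn stencil
replicates the nearest edge cells, so uniform and uniformly inclined
surfaces behave consistently to the border. All indices ignore constant
elevation shifts.

**Climatic instability.** Given climate panels for a chronological
sequence of periods ending at the present, the current panel is
standardized over cells and a PCA fitted to it once; every period is then
standardized *with the current means and SDs* and projected into that
fixed PC1–PC2 plane. Per cell, the Euclidean distance between each
period and the next is aggregated (mean, sum, or SD). Fitting the PCA
only once is deliberate: refitting per period would re-normalize away the
very displacement the statistic measures. Distances are invariant to
affine rescaling of any input variable (the standardization absorbs it)
and to PC sign flips. Variance explained by PC1–PC2 is recorded but not
thresholded. Two presets mirror common use: a coarse 4-period sequence
since the Last Inter-Glacial (mean only — with 3 steps an SD would be
noise) and a dense series since the Last Glacial Maximum (mean, sum, SD;
sum is exactly mean × (periods − 1), which the tests assert). The package
includes the current→most-recent-past step in the sequence; the period
list is an explicit argument, so other choices are one call away.

**Collinearity.** Correlation clustering (complete linkage on
$1 - |r|$, advisory) plus stepwise VIF removal: repeatedly drop the
largest-VIF layer (alphabetical tie-break, so runs are deterministic)
until max VIF ≤ 2.5. The retained set provably satisfies the ceiling;
VIFs are computed by least squares of each layer on the others.

# Spatial models

**Correlogram and weights.** Moran's I is evaluated per distance class
(binary pair weights, normal-approximation variance, two-sided p), on
contiguous classes of configurable width. The neighborhood radius
`d_max` for modelling is the upper bound of the first nonsignificant
class; if every class is significant the maximum distance is used with a
warning. A Bonferroni per-class correction is available and off by
default — it only shrinks `d_max`, and the uncorrected scan is the more
conservative choice for *detecting* residual autocorrelation. Weights
are distance-band neighbors, row-standardized; zero-neighbor cells are a
hard error unless explicitly dropped, because a spatial-error model is
undefined for them.

**Spatial-error SAR.** The model is
$y = X\beta + u,\ u = \lambda W u + \varepsilon$. "SAR" is used for
several specifications in the literature; this package implements the
*error* form only, since the scientific question is residual spatial
dependence, not endogenous spillover of the response. Estimation is
concentrated maximum likelihood: for trial $\lambda$, filtering by
$A = I - \lambda W$ reduces the problem to OLS on $(Ay, AX)$, and

$$\log L(\lambda) = \log|A| - \frac{n}{2}\left(\log 2\pi\hat\sigma^2(\lambda) + 1\right),$$

maximized by Brent search to $10^{-8}$ on
$(1/\omega_{min},\ 1/\omega_{max})$, the feasible interval from the
extreme eigenvalues of $W$. Because the row-standardized $W = D^{-1}B$ is
similar to the symmetric $D^{-1/2} B D^{-1/2}$, its spectrum is real and
the log-determinant is an exact cheap sum $\sum_i \log(1-\lambda\omega_i)$;
dense eigendecomposition is entirely adequate at the $10^3$-cell scale
this package targets. Coefficient standard errors are the GLS ones at the
ML $\lambda$ (the usual concentrated-likelihood convention; they do not
propagate uncertainty in $\lambda$ itself). AIC counts
$k = |\beta| + 2$ ($\lambda$ and $\sigma^2$); the +2 is a constant across
subsets of one response, so rankings are unaffected by the convention.
Fixing $\lambda = 0$ reproduces OLS exactly, which the tests use as an
oracle, alongside a dense-matrix likelihood oracle and a 100-seed
parameter-recovery simulation at $n = 900$, $\lambda = 0.6$.

**Model selection.** Every subset of up to 15 candidate predictors is
fitted (optionally with an always-in covariate such as the null-model
expected value, the `PD ~ PDnull + predictors` form) and ranked by AIC.
Goodness of fit is Nagelkerke's pseudo $R^2$,
$(1 - e^{-\frac{2}{n}(\ell_M-\ell_0)}) / (1 - e^{\frac{2}{n}\ell_0})$,
against the non-spatial intercept-only fit by default (a spatial null can
be supplied instead). With a continuous response the likelihood is a
density and can push the ratio marginally above 1; it is truncated to
$[0, 1]$. PE is log-transformed before modelling to tame its long right
tail; empty cells (PE = 0) are excluded before the transform, so the log
is always defined.

# Synthetic data and what it does (not) show

The generator draws a Yule (pure-birth) tree — the simplest ultrametric
generator; tree shape is not itself a tested quantity — and builds each
species' range by thresholding a suitability field (a weighted sum of a
driver environment layer and a species random field) at its target range
size, drawn log-normal. Quantile thresholding reproduces the skewed
range-size spectrum that drives PE without simulating dispersal;
micro-endemics are clamped to a cell plus its best neighbor.
Environmental layers are Gaussian random fields (FFT spectral method on
the grid torus, so correlation wraps at the edges — irrelevant at
correlation lengths well below the grid size), standardized per layer.
The paleoclimate series is a per-cell Gaussian random walk whose step SD
is the volatility layer; the instability statistic's rank correlation
with that layer (Spearman ≥ 0.9 on the 43-period series) is the
calibration the acceptance suite checks.

One master seed spawns named sub-streams (tree / env / ranges /
volatility / paleo), so e.g. changing the number of null replicates never
perturbs the simulated data, and a full pipeline rerun is bit-identical
on disk — asserted by hashing outputs.

What passing these tests shows: the metrics, nulls, instability statistic
and SAR machinery are internally correct and jointly able to recover
known drivers. What they do not show: anything about niche evolution,
dispersal limitation, sampling effort, or coastline/partial-cell effects,
none of which the generator emulates. Real-data quirks — detection bias,
taxonomic drift, projection distortion — are out of scope; coordinates
are abstract Euclidean map units throughout, and all declared cells are
treated identically.

# Numerical and design notes

* Null streaming statistics accumulate deviations from the observed
  value, so label-invariant cells get an exactly zero null SD instead of
  a cancellation-noise SD.
* On trend-dominated responses every correlogram class can be
  significant; the max-distance fallback then yields a near-complete,
  heavily averaged weights matrix, and the fitted $\lambda$ can be large
  and negative. Treat that as a diagnostic that a distance-band error
  model is a poor description of such a surface, not as an estimate to
  interpret.
* `align_layer` supports mean (source centers within the target square —
  conserves the global mean on nested exact-ratio grids), nearest, and
  bilinear resampling on the plain-text ESRI ASCII grid format; no
  reprojection is attempted.
* Problem sizes used in the shipped tests and acceptance script — $10^2$
  to $10^3$ cells, 100-seed simulation batches, 999–9999 permutation
  replicates — were chosen as the smallest scales at which the asserted
  statistical properties are stable.

# A short worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = simulation_config(n_species = 12, nx = 20, ny = 20,
                          n_paleo_periods = 20, seed = 3),
  n_reps = 99, seed = 3)
res <- run_pipeline(cfg)
res$log
head(res$models$PE$ranking$table)
```
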