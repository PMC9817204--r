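# phyloscape

Spatial phylogenetics on gridded communities: where is evolutionary
history concentrated, is that concentration more than random phylogenetic
structure would produce, and what environmental and topographic variables
drive it?

The package is aimed at biogeographers and macroecologists working with
regional atlas data — typically a few dozen species (amphibians are the
motivating group) scored present/absent on a regular grid of
10<sup>3</sup>–10<sup>4</sup> cells, plus a dated phylogeny and
environmental raster layers. Because such atlas compilations are usually
not redistributable, the package ships a synthetic-data generator with
known ground truth and validates the entire analysis chain against it.

## What it computes

For each grid cell *c* with species set *S<sub>c</sub>*, using the branch
set *B<sub>c</sub>* spanning *S<sub>c</sub>* to the root:

- **Phylogenetic diversity** (rooted Faith):
  *PD(c) = Σ<sub>b∈B<sub>c</sub></sub> L<sub>b</sub>*
- **Phylogenetic endemism** (range-weighted branch lengths):
  *PE(c) = Σ<sub>b∈B<sub>c</sub></sub> L<sub>b</sub>/R<sub>b</sub>*,
  where *R<sub>b</sub>* is the number of cells reached by branch *b*;
  every branch is fully apportioned, so Σ<sub>c</sub> PE(c) equals the
  pruned tree length
- **Weighted endemism**: *WE(c) = Σ<sub>s∈S<sub>c</sub></sub>
  1/R<sub>s</sub>*
- **Permutation nulls** (tip shuffle; fixed–fixed independent swap) with
  per-cell null mean/SD, *SES = (obs − mean)/sd*, and half-tie rank
  p-values; one-sided significance at *p* > .95
- **Predictors**: slope/TPI/TRI from a DEM (Horn 3×3, 8-neighbor
  window); climatic instability = per-cell Euclidean PC1–PC2
  displacement between consecutive paleoclimate periods, PCA fitted on
  current climate only; collinearity screening by correlation clustering
  and stepwise VIF (ceiling 2.5)
- **Spatial models**: Moran's I correlograms → distance-band
  row-standardized weights (neighborhood radius = first nonsignificant
  class) → maximum-likelihood spatial-error SAR
  (*y = Xβ + u*, *u = λWu + ε*) → exhaustive all-subsets AIC ranking
  with Nagelkerke pseudo R², optionally forcing the null-expected
  diversity into every model (`PD ~ PDnull + predictors`)

## Worked example

A small end-to-end run — 12 simulated species on a 20 × 20 grid, 99
tip-shuffle replicates, exhaustive SAR selection over the VIF-screened
predictor panel:

```r
library(phyloscape)
cfg <- pipeline_config(
  sim = simulation_config(n_species = 12, nx = 20, ny = 20,
                          n_paleo_periods = 20, seed = 3),
  n_reps = 99, seed = 3)
res <- run_pipeline(cfg)
res$log
#> [1] "simulated 12 species on 400 cells"
#> [2] "removed restricted species: sp001"
#> [3] "VIF screening retained: env1, env3, altitude, slope, tpi, tri, lgm_sd"
#> [4] "190 empty cells and 0 incomplete-predictor cells excluded from modelling"
head(res$models$PE$ranking$table, 3)
#>                               model  k logLik   AIC lambda     r2   dAIC
#> 1              env1+env3+tri+lgm_sd  8 -29.45 74.90 0.7147 0.9639 0.0000
#> 2     env1+env3+altitude+tri+lgm_sd  9 -28.52 75.04 0.6673 0.9652 0.1413
#> 3 env1+env3+altitude+tpi+tri+lgm_sd 10 -27.94 75.88 0.6895 0.9660 0.9756
res$models$PE$ranking$best_coefficients
#>           term estimate     se      z        p stars
#> 1  (Intercept)  -2.9158 0.0675 -43.22 0.00e+00   ***
#> 2 pe_null_mean   0.5755 0.0273  21.11 6.24e-99   ***
#> 3         env1   0.1464 0.0308   4.74 2.09e-06   ***
#> 4         env3   0.1637 0.0351   4.66 3.18e-06   ***
#> 5          tri   0.0474 0.0222   2.14 3.25e-02     *
#> 6       lgm_sd  -0.0713 0.0242  -2.94 3.25e-03    **
```

Reading this: the one micro-endemic (`sp001`, ≤ 2 cells) was filtered
before modelling; of the collinear predictor panel, seven layers survive
the VIF 2.5 screen (the LGM-instability *sum* is dropped as an exact
multiple of its *mean*); the AIC-best model for log-PE keeps the true
simulated driver `env1` with a positive coefficient, alongside the
always-in null-expectation covariate, with spatial-error
λ ≈ 0.71 soaking up the residual autocorrelation. Coefficients are on
scaled predictors, so they are comparable in magnitude.

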