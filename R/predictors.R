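#' Terrain indices from a digital elevation model
#'
#' Computes, on an 8-neighbor (queen) moving window over a regular
#' rectangular grid:
#' * slope, from Horn's 3x3 finite differences, in degrees;
#' * TPI (topographic position index), the cell elevation minus the mean of
#'   its available neighbors;
#' * TRI (terrain ruggedness index), the mean absolute elevation difference
#'   to the available neighbors.
#'
#' Edge cells use whichever neighbors exist; for the Horn slope stencil the
#' out-of-grid cells are replicated from the nearest edge, which makes a
#' flat or uniformly inclined surface behave consistently up to the border.
#' All three indices ignore any constant shift of the DEM.
#'
#' @param grid a `ps_grid` forming a complete rectangular lattice of at
#'   least 2 rows and 2 columns.
#' @param dem elevation layer on `grid` (map-unit-consistent z, e.g. m).
#' @return list of `ps_layer`s: `slope` (degrees), `tpi`, `tri` (z units).
#' @export
terrain_indices <- function(grid, dem) {
  lay <- grid_layout(grid)
  if (lay$nx < 2 || lay$ny < 2)
    stop("terrain indices need a grid of at least 2 x 2 cells")
  z <- layer_matrix(grid, dem)
  ny <- nrow(z); nx <- ncol(z)
  cs <- cell_size(grid)
  # neighbor stacks via index shifting with edge replication
  shift <- function(m, dy, dx, replicate_edge = FALSE) {
    ri <- seq_len(ny) + dy; ci <- seq_len(nx) + dx
    if (replicate_edge) {
      ri <- pmin(pmax(ri, 1L), ny); ci <- pmin(pmax(ci, 1L), nx)
      m[ri, ci, drop = FALSE]
    } else {
      out <- matrix(NA_real_, ny, nx)
      ok_r <- ri >= 1 & ri <= ny; ok_c <- ci >= 1 & ci <= nx
      out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c], drop = FALSE]
      out
    }
  }
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  nb_sum <- matrix(0, ny, nx); nb_n <- matrix(0, ny, nx)
  tri_sum <- matrix(0, ny, nx)
  for (k in seq_len(nrow(offs))) {
    nb <- shift(z, offs$dy[k], offs$dx[k])
    ok <- !is.na(nb)
    nb_sum[ok] <- nb_sum[ok] + nb[ok]
    tri_sum[ok] <- tri_sum[ok] + abs(nb[ok] - z[ok])
    nb_n <- nb_n + ok
  }
  tpi <- z - nb_sum / nb_n
  tri <- tri_sum / nb_n
  # Horn slope with edge replication; window letters
  #   a b c          (row +1 = larger y = "north")
  #   d z f
  #   g h i
  a <- shift(z,  1, -1, TRUE); b <- shift(z,  1, 0, TRUE); cc <- shift(z,  1, 1, TRUE)
  d <- shift(z,  0, -1, TRUE);                             f  <- shift(z,  0, 1, TRUE)
  g <- shift(z, -1, -1, TRUE); h <- shift(z, -1, 0, TRUE); i  <- shift(z, -1, 1, TRUE)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  list(slope = matrix_layer(grid, slope, "slope", "degrees"),
       tpi = matrix_layer(grid, tpi, "tpi", attr(dem, "units") %||% ""),
       tri = matrix_layer(grid, tri, "tri", attr(dem, "units") %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Climatic instability from a time series of climate panels
#'
#' Instability is measured in the principal-component space of the CURRENT
#' climate: the current variables are standardized over cells and a PCA is
#' fitted to them once; every period's variables are then standardized with
#' the current means/sds and projected onto PC1-PC2 of that fixed space, so
#' that climate change itself, not re-normalization, drives the distances.
#' Per cell, the Euclidean distance in (PC1, PC2) between each period and
#' the chronologically next one is computed and aggregated.
#'
#' @param periods named list, ordered oldest to present (the LAST element is
#'   the current climate), each element a cells-by-variables numeric matrix;
#'   all periods must share the same variable set.
#' @param aggregate which per-cell summaries of the step distances to
#'   return: any of `"mean"`, `"sum"`, `"sd"`.
#' @return a data frame with one row per cell and one column per requested
#'   aggregate (PC-score units); attribute `variance_explained` holds the
#'   PC1-PC2 share of the current-climate variance.
#' @export
pca_instability <- function(periods, aggregate = c("mean", "sum", "sd")) {
  aggregate <- match.arg(aggregate, several.ok = TRUE)
  if (length(periods) < 2)
    stop("instability needs at least 2 periods (including current)")
  vars <- colnames(periods[[length(periods)]])
  if (is.null(vars)) stop("period matrices must have variable column names")
  for (i in seq_along(periods)) {
    if (!identical(sort(colnames(periods[[i]])), sort(vars)))
      stop("period ", names(periods)[i] %||% i,
           " has mismatched variables")
    periods[[i]] <- as.matrix(periods[[i]])[, vars, drop = FALSE]
  }
  cur <- periods[[length(periods)]]
  mu <- colMeans(cur)
  sd <- apply(cur, 2, stats::sd)
  zero <- sd <= 1e-12 * (1 + abs(mu))
  if (any(zero))
    stop("constant current-climate variable(s): ",
         paste(vars[zero], collapse = ", "))
  std <- function(m) sweep(sweep(m, 2, mu), 2, sd, "/")
  pca <- stats::prcomp(std(cur), center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  scores <- lapply(periods, function(m) std(m) %*% rot)
  n_step <- length(periods) - 1
  steps <- matrix(0, nrow = nrow(cur), ncol = n_step)
  for (t in seq_len(n_step)) {
    d <- scores[[t + 1]] - scores[[t]]
    steps[, t] <- sqrt(rowSums(d^2))
  }
  out <- data.frame(row.names = NULL,
                    lapply(stats::setNames(aggregate, aggregate), function(a)
                      switch(a,
                             mean = rowMeans(steps),
                             sum = rowSums(steps),
                             sd = if (n_step >= 2) apply(steps, 1, stats::sd)
                                  else rep(0, nrow(steps)))))
  ve <- sum(pca$sdev[seq_len(k)]^2) / sum(pca$sdev^2)
  attr(out, "variance_explained") <- ve
  attr(out, "n_steps") <- n_step
  out
}

#' Instability since the Last Inter-Glacial
#'
#' Mean per-cell PC1-PC2 step distance over the coarse 4-period sequence
#' 120 ky -> 21 ky -> 6 ky -> present, on the full bioclimatic panel.
#'
#' @param grid a `ps_grid` (layer binding only).
#' @param current,ky6,ky21,ky120 cells-by-variables matrices sharing one
#'   variable set.
#' @return a `ps_layer` of mean instability (PC-score units).
#' @export
lig_instability <- function(grid, current, ky6, ky21, ky120) {
  inst <- pca_instability(list(`120ky` = ky120, `21ky` = ky21,
                               `6ky` = ky6, current = current),
                          aggregate = "mean")
  new_layer(grid, inst$mean, name = "lig_instability", units = "PC score")
}

#' Instability since the Last Glacial Maximum
#'
#' Mean, sum and sd of per-cell PC1-PC2 step distances over a dense
#' (e.g. 500-year) series from the LGM to the present, on a restricted
#' climate panel (precipitation plus max/min temperature stand-ins).
#'
#' @param grid a `ps_grid`.
#' @param series named list of cells-by-variables matrices, ordered oldest
#'   to present (last = current), length >= 2.
#' @return list of `ps_layer`s `mean`, `sum`, `sd`.
#' @export
lgm_instability <- function(grid, series) {
  inst <- pca_instability(series, aggregate = c("mean", "sum", "sd"))
  list(mean = new_layer(grid, inst$mean, "lgm_mean_instability", "PC score"),
       sum = new_layer(grid, inst$sum, "lgm_sum_instability", "PC score"),
       sd = new_layer(grid, inst$sd, "lgm_sd_instability", "PC score"))
}

#' Group collinear predictors by correlation clustering
#'
#' Complete-linkage hierarchical clustering on the distance 1 - |r| of the
#' pairwise Pearson correlations, cut so that layers correlated above the
#' cutoff (in absolute value) fall in one group. Advisory: the screening
#' that actually drops predictors is [vif_stepwise()].
#'
#' @param panel cells-by-layers numeric matrix or data frame.
#' @param cut absolute-correlation grouping threshold (default 0.7).
#' @return data frame `layer`, `cluster`; the `hclust` object is attached
#'   as attribute `hclust`.
#' @export
correlation_cluster <- function(panel, cut = 0.7) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 2) stop("need at least 2 layers to cluster")
  r <- stats::cor(panel, use = "pairwise.complete.obs")
  h <- stats::hclust(stats::as.dist(1 - abs(r)), method = "complete")
  grp <- stats::cutree(h, h = 1 - cut)
  out <- data.frame(layer = names(grp), cluster = unname(grp),
                    stringsAsFactors = FALSE)
  attr(out, "hclust") <- h
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j comes from the least-squares
#' regression of layer j on all other layers (plus an intercept). A layer
#' perfectly explained by the others gets `Inf`.
#'
#' @param panel cells-by-layers numeric matrix or data frame (complete
#'   cases are used).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(panel) {
  panel <- as.matrix(panel)
  panel <- panel[stats::complete.cases(panel), , drop = FALSE]
  p <- ncol(panel)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(panel)))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, panel[, -j, drop = FALSE]), panel[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((panel[, j] - mean(panel[, j]))^2)
    if (tss <= 0) return(NA_real_)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(panel))
}

#' Stepwise VIF screening
#'
#' Repeatedly drops the layer with the largest VIF (alphabetical tie-break)
#' until the largest VIF is at most `threshold`. The retained set therefore
#' always satisfies max VIF <= threshold; with fewer than 2 layers the panel
#' is returned unchanged.
#'
#' @param panel cells-by-layers numeric matrix or data frame.
#' @param threshold VIF ceiling (default 2.5).
#' @return list with `retained` (layer names), `dropped`, and `log` (a data
#'   frame of each step's dropped layer and its VIF).
#' @export
vif_stepwise <- function(panel, threshold = 2.5) {
  panel <- as.matrix(panel)
  keep <- colnames(panel)
  log <- data.frame(step = integer(), dropped = character(),
                    vif = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (length(keep) >= 2) {
    v <- vif(panel[, keep, drop = FALSE])
    if (max(v) <= threshold) break
    step <- step + 1L
    worst <- sort(names(v)[v == max(v)])[1]
    log <- rbind(log, data.frame(step = step, dropped = worst,
                                 vif = unname(v[worst])))
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, dropped = setdiff(colnames(panel), keep), log = log)
}

#' Scale a predictor panel to zero mean, unit sd
#'
#' @param panel cells-by-layers numeric matrix or data frame.
#' @return matrix with each column centered and scaled; the per-layer means
#'   and sds are kept in attribute `scaling` for back-transformation.
#' @export
scale_panel <- function(panel) {
  panel <- as.matrix(panel)
  mu <- colMeans(panel, na.rm = TRUE)
  sd <- apply(panel, 2, stats::sd, na.rm = TRUE)
  if (any(sd <= 0, na.rm = TRUE))
    stop("constant layer(s): ",
         paste(colnames(panel)[sd <= 0], collapse = ", "))
  out <- sweep(sweep(panel, 2, mu), 2, sd, "/")
  attr(out, "scaling") <- data.frame(layer = colnames(panel),
                                     mean = unname(mu), sd = unname(sd))
  out
}
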