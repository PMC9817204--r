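#' Synthetic study-system configuration
#'
#' Bundles every knob of the synthetic generator. The defaults describe the
#' kind of regional amphibian system the package targets: 27 species on a
#' 32 x 32 grid (1024 cells, each standing for a 10 km square in abstract
#' map units), a Yule tree, smooth environmental gradients, a strongly
#' right-skewed range-size distribution with one extreme micro-endemic
#' confined to at most 2 cells, and a dense paleoclimate random-walk series.
#' One master seed deterministically spawns named sub-streams (tree, env,
#' ranges, paleo), so each component can be regenerated independently.
#'
#' @param n_species number of species (>= 2).
#' @param nx,ny grid dimensions in cells (>= 2).
#' @param cell_size cell edge length in map units.
#' @param birth_rate Yule speciation rate (per branch-length unit).
#' @param autocorr_length Gaussian-kernel correlation length of the
#'   environmental random fields, in cells.
#' @param n_env number of environmental layers.
#' @param range_meanlog,range_sdlog log-normal parameters of the target
#'   range size, in cells.
#' @param n_micro_endemics species clamped to at most 2 contiguous cells.
#' @param env_effect strength of the environmental driver on species
#'   suitability (0 = ranges independent of the environment).
#' @param driver_layer index of the env layer that drives suitability.
#' @param n_paleo_periods number of paleoclimate time slices (>= 2).
#' @param n_paleo_vars climate variables per paleo slice.
#' @param volatility_scale multiplier on the per-cell paleo step sd.
#' @param seed master integer seed.
#' @return a validated list of class `ps_config`.
#' @export
simulation_config <- function(n_species = 27, nx = 32, ny = 32,
                              cell_size = 1, birth_rate = 1,
                              autocorr_length = 5, n_env = 3,
                              range_meanlog = log(60), range_sdlog = 1.2,
                              n_micro_endemics = 1, env_effect = 1,
                              driver_layer = 1, n_paleo_periods = 43,
                              n_paleo_vars = 3, volatility_scale = 1,
                              seed = 1) {
  stopifnot(n_species >= 2, nx >= 2, ny >= 2, cell_size > 0,
            birth_rate > 0, n_micro_endemics < n_species,
            n_micro_endemics >= 0, n_paleo_periods >= 2,
            driver_layer >= 1, driver_layer <= n_env)
  structure(as.list(environment()), class = "ps_config")
}

# Deterministic sub-seed for a named stream, < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483629 + 1)
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree via [ape::rphylo()] (death rate 0), tips relabelled
#' `sp001 ...` in tip order. Deterministic per seed.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return an ultrametric `phylo`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# Gaussian random field on an ny x nx torus by FFT spectral convolution of
# white noise with a Gaussian kernel of sd `len` cells; len ~ 0 gives white
# noise. Returned standardized to sample mean 0, sd 1.
gaussian_field <- function(nx, ny, len) {
  noise <- matrix(stats::rnorm(nx * ny), ny, nx)
  if (len <= 1e-9) {
    f <- noise
  } else {
    dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
    dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
    kern <- exp(-outer(dy^2, dx^2, "+") / (2 * len^2))
    f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
      (nx * ny)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Simulate spatially autocorrelated environmental layers
#'
#' Standardized Gaussian random fields (spectral method on the grid torus)
#' with a common correlation length; each layer has sample mean 0, sd 1.
#'
#' @param grid a rectangular `ps_grid`.
#' @param n_layers number of layers.
#' @param autocorr_length kernel sd in cells (near 0 = white noise).
#' @param seed integer seed.
#' @return list of `ps_layer`s named `env1 ...`.
#' @export
simulate_env_layers <- function(grid, n_layers, autocorr_length = 5,
                                seed = 1) {
  lay <- grid_layout(grid)
  set.seed(seed)
  out <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    f <- gaussian_field(lay$nx, lay$ny, autocorr_length)
    out[[k]] <- matrix_layer(grid, f, name = paste0("env", k))
  }
  names(out) <- paste0("env", seq_len(n_layers))
  out
}

#' Simulate a paleoclimate time series as a per-cell random walk
#'
#' Period t equals period t-1 plus independent Gaussian noise whose
#' per-cell standard deviation is the volatility layer, applied to every
#' climate variable; cells with volatility 0 are constant through time.
#' Periods are returned oldest to present.
#'
#' @param grid a `ps_grid`.
#' @param n_periods number of time slices (>= 2).
#' @param volatility per-cell step sd (a `ps_layer` or numeric vector,
#'   all values >= 0).
#' @param n_vars number of climate variables.
#' @param seed integer seed.
#' @param init optional cells-by-vars matrix for the oldest period
#'   (default: independent standard-normal fields).
#' @return named list of cells-by-vars matrices, oldest first.
#' @export
simulate_paleo_series <- function(grid, n_periods, volatility, n_vars = 3,
                                  seed = 1, init = NULL) {
  if (n_periods < 2) stop("paleo series needs at least 2 periods")
  vol <- as.numeric(volatility)
  stopifnot(length(vol) == nrow(grid), all(vol >= 0))
  set.seed(seed)
  n <- nrow(grid)
  if (is.null(init))
    init <- matrix(stats::rnorm(n * n_vars), n, n_vars)
  colnames(init) <- paste0("clim", seq_len(n_vars))
  out <- vector("list", n_periods)
  out[[1]] <- init
  for (t in 2:n_periods) {
    step <- matrix(stats::rnorm(n * n_vars), n, n_vars) * vol
    out[[t]] <- out[[t - 1]] + step
    colnames(out[[t]]) <- colnames(init)
  }
  names(out) <- sprintf("t%03d", seq_len(n_periods))
  out
}

#' Simulate species ranges by quantile-thresholded suitability
#'
#' Each species gets a suitability field: `env_effect` times the driver
#' environmental layer plus a species-specific Gaussian random field. The
#' species occupies its top-n cells, n drawn from a log-normal target
#' range-size distribution (clamped to the grid), which reproduces the
#' right-skewed range-size spectrum that drives endemism. The first
#' `n_micro_endemics` species are instead clamped to at most 2 contiguous
#' cells (a cell and its best neighbor). Every species occupies >= 1 cell.
#'
#' @param grid a rectangular `ps_grid`.
#' @param tree `phylo` whose tips name the species.
#' @param env list of environmental `ps_layer`s (driver selected by config).
#' @param config a `ps_config`.
#' @param seed integer seed.
#' @return a `ps_occ` occurrence matrix.
#' @export
simulate_ranges <- function(grid, tree, env, config, seed = 1) {
  set.seed(seed)
  lay <- grid_layout(grid)
  n <- nrow(grid)
  sp <- tree$tip.label
  driver <- as.numeric(env[[config$driver_layer]])
  m <- matrix(0L, n, length(sp), dimnames = list(grid$cell_id, sp))
  targets <- pmin(pmax(round(stats::rlnorm(length(sp),
                                           config$range_meanlog,
                                           config$range_sdlog)), 1), n)
  micro <- seq_len(config$n_micro_endemics)
  for (s in seq_along(sp)) {
    suit <- config$env_effect * driver +
      as.numeric(matrix_layer(grid, gaussian_field(lay$nx, lay$ny,
                                                   config$autocorr_length)))
    if (s %in% micro) {
      seed_cell <- sample.int(n, 1)
      nb <- which(abs(grid$x - grid$x[seed_cell]) <= cell_size(grid) * 1.01 &
                    abs(grid$y - grid$y[seed_cell]) <= cell_size(grid) * 1.01)
      nb <- setdiff(nb, seed_cell)
      cells <- c(seed_cell, nb[which.max(suit[nb])])
      cells <- cells[seq_len(min(2, length(cells)))]
    } else {
      cells <- order(suit, decreasing = TRUE)[seq_len(targets[s])]
    }
    m[cells, s] <- 1L
  }
  as_ps_occ(m, grid)
}

#' Generate a complete synthetic study system
#'
#' Orchestrates tree, environment, ranges, a volatility layer and a
#' paleoclimate series from one master seed (named sub-streams), returning
#' the known ground truth alongside the data.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `grid`, `tree`, `env` (list of layers),
#'   `occ`, `volatility` (layer), `paleo` (period list), and `truth`
#'   (driver layer name, env effect, volatility description).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "ps_config"))
  grid <- make_grid(config$nx, config$ny, config$cell_size)
  tree <- simulate_tree(config$n_species, config$birth_rate,
                        seed = derive_seed(config$seed, "tree"))
  env <- simulate_env_layers(grid, config$n_env, config$autocorr_length,
                             seed = derive_seed(config$seed, "env"))
  occ <- simulate_ranges(grid, tree, env, config,
                         seed = derive_seed(config$seed, "ranges"))
  set.seed(derive_seed(config$seed, "volatility"))
  lay <- grid_layout(grid)
  vol_field <- gaussian_field(lay$nx, lay$ny, config$autocorr_length)
  vol <- matrix_layer(grid, (vol_field - min(vol_field)) /
                        (max(vol_field) - min(vol_field)) *
                        config$volatility_scale,
                      name = "volatility")
  paleo <- simulate_paleo_series(grid, config$n_paleo_periods, vol,
                                 n_vars = config$n_paleo_vars,
                                 seed = derive_seed(config$seed, "paleo"))
  list(config = config, grid = grid, tree = tree, env = env, occ = occ,
       volatility = vol, paleo = paleo,
       truth = list(driver = names(env)[config$driver_layer],
                    env_effect = config$env_effect,
                    volatility_scale = config$volatility_scale))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `tree.nwk`, `grid.csv`, `occurrences.csv` (long format),
#' `env_<name>.asc`, `paleo_<period>_<var>.asc`, `volatility.asc` and
#' `truth.json` into a directory.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(serialize_newick(dataset$tree), file.path(dir, "tree.nwk"))
  utils::write.csv(as.data.frame(dataset$grid), file.path(dir, "grid.csv"),
                   row.names = FALSE, quote = FALSE)
  idx <- which(dataset$occ == 1L, arr.ind = TRUE)
  long <- data.frame(cell_id = rownames(dataset$occ)[idx[, 1]],
                     species = colnames(dataset$occ)[idx[, 2]])
  long <- long[order(long$cell_id, long$species), ]
  utils::write.csv(long, file.path(dir, "occurrences.csv"),
                   row.names = FALSE, quote = FALSE)
  grid <- dataset$grid
  as_raster <- function(layer) {
    lay <- grid_layout(grid)
    m <- layer_matrix(grid, layer)
    list(values = m[rev(seq_len(nrow(m))), , drop = FALSE],
         xll = min(grid$x) - cell_size(grid) / 2,
         yll = min(grid$y) - cell_size(grid) / 2,
         cellsize = cell_size(grid))
  }
  for (nm in names(dataset$env))
    write_asc(as_raster(dataset$env[[nm]]),
              file.path(dir, paste0("env_", nm, ".asc")))
  write_asc(as_raster(dataset$volatility), file.path(dir, "volatility.asc"))
  for (pd in names(dataset$paleo))
    for (v in colnames(dataset$paleo[[pd]]))
      write_asc(as_raster(new_layer(grid, dataset$paleo[[pd]][, v])),
                file.path(dir, paste0("paleo_", pd, "_", v, ".asc")))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
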