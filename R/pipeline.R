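#' Pipeline configuration
#'
#' A single validated object driving the full analysis: simulate (or load) a
#' study system, compute diversity metrics, run permutation nulls, derive
#' and screen predictors, and select spatial-error SAR models per response.
#' All randomness flows from `seed` through named per-stage sub-streams, so
#' re-running the same configuration is bit-identical and changing e.g. the
#' number of null replicates does not perturb the simulated data.
#'
#' @param sim a [simulation_config()] describing the synthetic system.
#' @param responses which diversity responses to model: subset of
#'   `"PD"`, `"PE"` (PE is log-transformed before modelling).
#' @param null null model for the expected-diversity covariate:
#'   `"tip_shuffle"` or `"independent_swap"`.
#' @param n_reps permutation replicates (999 in a full analysis; smaller
#'   for demos).
#' @param use_null_covariate include the per-cell null mean as an
#'   always-in covariate (the `PD ~ PDnull + predictors` form).
#' @param min_range_cells range-restriction filter passed to
#'   [filter_restricted_species()].
#' @param vif_threshold stepwise VIF ceiling.
#' @param increment correlogram distance-class width, in map units.
#' @param max_candidates cap on SAR candidate predictors (<= 15).
#' @param drop_islands passed to [build_weights()].
#' @param out_dir optional directory; when given, all stage tables are
#'   written as CSV/JSON with a provenance file of MD5 hashes.
#' @param seed master seed.
#' @return a list of class `ps_pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            responses = c("PD", "PE"),
                            null = c("tip_shuffle", "independent_swap"),
                            n_reps = 99, use_null_covariate = TRUE,
                            min_range_cells = 3, vif_threshold = 2.5,
                            increment = NULL, max_candidates = 15,
                            drop_islands = FALSE, out_dir = NULL, seed = 1) {
  null <- match.arg(null)
  responses <- match.arg(responses, several.ok = TRUE)
  stopifnot(inherits(sim, "ps_config"), n_reps >= 1,
            max_candidates <= 15, vif_threshold > 1)
  if (is.null(increment)) increment <- 1.05 * sim$cell_size
  structure(as.list(environment()), class = "ps_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate -> filter restricted species -> diversity table ->
#' permutation nulls -> predictor derivation (terrain indices from a
#' synthetic DEM, LGM-style instability from the paleo series) ->
#' collinearity screening (correlation clusters, stepwise VIF) ->
#' per-response Moran correlogram, distance-band weights and exhaustive
#' SAR subset selection. Cells with zero species, and cells missing any
#' retained predictor, are excluded from the modelling stage (logged).
#'
#' @param config a [pipeline_config()].
#' @return a result bundle: `data` (the synthetic system), `diversity`,
#'   `removed_species`, `nulls` (per response), `screening` (clusters, VIF
#'   log, retained set), `models` (per response: correlogram, `d_max`,
#'   ranking), `modelled_cells`, and `log` (per-stage notes). Written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ps_pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  data <- simulate_dataset(sim)
  grid <- data$grid
  note("simulated ", ncol(data$occ), " species on ", nrow(grid), " cells")

  filt <- filter_restricted_species(data$occ, config$min_range_cells)
  occ <- filt$occ
  if (nrow(filt$removed))
    note("removed restricted species: ",
         paste(filt$removed$species, collapse = ", "))
  div <- diversity_table(data$tree, occ)

  nulls <- lapply(stats::setNames(config$responses, config$responses),
                  function(metric) {
    classify_significant(null_distribution(
      data$tree, occ, metric = metric, null = config$null,
      n_reps = config$n_reps,
      seed = derive_seed(config$seed, paste0("null_", metric))))
  })

  # predictor panel: environment, terrain from a synthetic DEM, instability
  set.seed(derive_seed(config$seed, "dem"))
  lay <- grid_layout(grid)
  dem <- matrix_layer(grid,
                      800 + 400 * gaussian_field(lay$nx, lay$ny,
                                                 sim$autocorr_length),
                      name = "altitude", units = "m")
  terr <- terrain_indices(grid, dem)
  lgm <- lgm_instability(grid, lapply(data$paleo, identity))
  panel <- cbind(do.call(cbind, lapply(data$env, as.numeric)),
                 altitude = as.numeric(dem),
                 slope = as.numeric(terr$slope),
                 tpi = as.numeric(terr$tpi),
                 tri = as.numeric(terr$tri),
                 lgm_mean = as.numeric(lgm$mean),
                 lgm_sum = as.numeric(lgm$sum),
                 lgm_sd = as.numeric(lgm$sd))
  rownames(panel) <- grid$cell_id
  clusters <- correlation_cluster(panel)
  screen <- vif_stepwise(panel, config$vif_threshold)
  note("VIF screening retained: ", paste(screen$retained, collapse = ", "))
  retained <- panel[, screen$retained, drop = FALSE]

  # modelled cells: occupied, complete predictor cases
  occupied <- div$richness > 0
  complete <- stats::complete.cases(retained)
  keep <- occupied & complete
  note(sum(!occupied), " empty cells and ", sum(occupied & !complete),
       " incomplete-predictor cells excluded from modelling")
  cand_all <- scale_panel(retained[keep, , drop = FALSE])
  if (ncol(cand_all) > config$max_candidates)
    cand_all <- cand_all[, seq_len(config$max_candidates), drop = FALSE]
  coords <- as.matrix(grid[keep, c("x", "y")])
  rownames(coords) <- grid$cell_id[keep]

  models <- lapply(stats::setNames(config$responses, config$responses),
                   function(metric) {
    y <- if (metric == "PD") div$pd[keep] else log(div$pe[keep])
    corr <- correlogram(y, coords, increment = config$increment)
    d_max <- neighbor_threshold(corr)
    w <- build_weights(coords, d_max, drop_islands = config$drop_islands)
    sel <- match(w$ids, rownames(coords))
    extra <- NULL
    if (config$use_null_covariate) {
      nm <- nulls[[metric]]$null_mean[keep][sel]
      extra <- cbind(scale(nm))
      colnames(extra) <- paste0(tolower(metric), "_null_mean")
    }
    ranking <- all_subsets_selection(y[sel],
                                     cand_all[sel, , drop = FALSE], w,
                                     extra_fixed = extra)
    list(correlogram = corr, d_max = d_max, weights = w, ranking = ranking)
  })

  out <- list(data = data, diversity = div, removed_species = filt$removed,
              nulls = nulls,
              screening = list(clusters = clusters, vif = screen,
                               scaling = attr(cand_all, "scaling")),
              predictor_panel = retained,
              models = models, modelled_cells = grid$cell_id[keep],
              log = log)
  if (!is.null(config$out_dir)) write_pipeline(out, config)
  out
}

write_pipeline <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$diversity, file.path(dir, "diversity.csv"),
                   row.names = FALSE, quote = FALSE)
  for (metric in names(result$nulls))
    utils::write.csv(result$nulls[[metric]],
                     file.path(dir, paste0("null_", tolower(metric), ".csv")),
                     row.names = FALSE, quote = FALSE)
  for (metric in names(result$models)) {
    m <- result$models[[metric]]
    utils::write.csv(as.data.frame(m$correlogram),
                     file.path(dir, paste0("correlogram_",
                                           tolower(metric), ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(m$ranking$table,
                     file.path(dir, paste0("sar_ranking_",
                                           tolower(metric), ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(m$ranking$best_coefficients,
                     file.path(dir, paste0("sar_best_",
                                           tolower(metric), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(retained = result$screening$vif$retained,
         dropped = result$screening$vif$dropped,
         vif_log = result$screening$vif$log,
         clusters = result$screening$clusters),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(lapply(unclass(cfg), function(x)
    if (is.atomic(x) || is.list(x)) x else as.character(x)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(dir, full.names = TRUE),
                   file.path(dir, "provenance.json"))
  prov <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
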