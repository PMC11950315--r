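# End-to-end pipeline: simulate -> indices -> rank-models -> changes -> chi
# -> risk -> coastal, every intermediate written as CSV in the work
# directory, with a JSON run manifest recording the configuration hash, the
# seed, and a digest of every stage output. Deterministic stages are pure
# functions of their declared inputs, so re-running with the same config and
# seed reproduces byte-identical outputs.

#' Run the full synthetic heatwave analysis
#'
#' Generates the synthetic ensemble defined by `config`, computes annual
#' heatwave indices for the baseline and the four future (scenario x window)
#' combinations with thresholds held fixed at each model's own baseline,
#' ranks the models against the reference series and selects those above the
#' half-maximum score, computes regional percentage-change ensemble series
#' and trends, builds per-model and ensemble CHI for every period (selected
#' models only), overlays CHI with the SSP population trajectories for the
#' 2050/2090 horizons, and classifies cities as coastal or inland.
#'
#' @param config an [analysis_config()].
#' @param workdir output directory (created if absent).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `workdir`.
#' @export
run_all <- function(config = analysis_config(), workdir = tempfile("heatscape_")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(workdir, f)
  stages <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  record <- function(stage, files) {
    stages[[stage]] <<- list(stage = stage,
                             outputs = as.list(basename(files)),
                             md5 = as.list(unname(tools::md5sum(files))))
  }

  spec <- synthetic_spec(n_cities = config$n_cities,
                         n_models = config$n_models,
                         seed = config$rng_seed)
  wins <- config$windows

  # --- simulate -------------------------------------------------------------
  log_stage("simulate", sprintf("%d cities x %d models, seed %d",
                                spec$n_cities, spec$n_models, spec$seed))
  data.table::fwrite(spec$cities[, c("city_id", "name", "region", "lon",
                                     "lat", "coast_group")],
                     outfile("cities.csv"))
  population <- generate_population(spec)
  data.table::fwrite(population, outfile("population.csv"))
  coastline <- generate_coastline(spec)
  write_coastline(coastline, outfile("coastline.geojson"))

  baseline <- generate_model_ensemble(spec, "historical", wins$baseline,
                                      include_reference = TRUE)
  future_sets <- list()
  for (scen in c("ssp245", "ssp585")) {
    for (wlbl in c("near_future", "far_future")) {
      future_sets[[paste(scen, wlbl, sep = ".")]] <-
        generate_model_ensemble(spec, scen, wins[[wlbl]],
                                include_reference = FALSE)
    }
  }
  sim_files <- outfile(c("cities.csv", "population.csv", "coastline.geojson"))
  if (config$write_daily) {
    write_daily_series(baseline, outfile("daily_baseline.csv"))
    sim_files <- c(sim_files, outfile("daily_baseline.csv"))
  }
  record("simulate", sim_files)

  # --- indices --------------------------------------------------------------
  log_stage("indices", "annual heatwave indices (thresholds fixed at baseline)")
  idx_base <- compute_annual_indices(baseline, baseline, wins$baseline,
                                     q = config$percentile_q,
                                     min_event_days = config$min_event_days)
  idx_fut <- lapply(future_sets, function(coll) {
    compute_annual_indices(coll, baseline, wins$baseline,
                           q = config$percentile_q,
                           min_event_days = config$min_event_days)
  })
  indices <- rbind(idx_base, do.call(rbind, idx_fut))
  rownames(indices) <- NULL
  write_table(indices, outfile("indices.csv"), kind = "indices")
  record("indices", outfile("indices.csv"))

  # --- period means ---------------------------------------------------------
  pm_base <- period_mean_indices(idx_base, wins$baseline)
  pm_fut <- list()
  for (scen in c("ssp245", "ssp585")) {
    for (wlbl in c("near_future", "far_future")) {
      pm <- period_mean_indices(idx_fut[[paste(scen, wlbl, sep = ".")]],
                                wins[[wlbl]])
      pm$period <- wlbl
      pm_fut[[paste(scen, wlbl, sep = ".")]] <- pm
    }
  }
  pm_base$period <- "baseline"
  period_means <- rbind(pm_base, do.call(rbind, pm_fut))
  rownames(period_means) <- NULL
  data.table::fwrite(period_means, outfile("period_means.csv"))
  record("period_means", outfile("period_means.csv"))

  # --- rank-models ----------------------------------------------------------
  log_stage("rank-models", "scoring against the reference series")
  ref_means <- pm_base[pm_base$model_id == .REFERENCE_MODEL, ]
  mod_means <- pm_base[pm_base$model_id != .REFERENCE_MODEL, ]
  ranking <- rank_models(mod_means, ref_means,
                         selection_fraction = config$selection_fraction)
  write_table(ranking$scores, outfile("scores.csv"), kind = "scores")
  record("rank-models", outfile("scores.csv"))
  selected <- ranking$scores$model_id[ranking$scores$selected]
  if (!length(selected)) {
    log_stage("rank-models", "no model surpasses the threshold; using all")
    selected <- ranking$scores$model_id
  }

  # --- changes --------------------------------------------------------------
  log_stage("changes", "regional percentage-change ensemble series")
  region_map <- spec$cities[, c("city_id", "region")]
  annual_fut <- do.call(rbind, idx_fut)
  base_means_models <- pm_base[pm_base$model_id != .REFERENCE_MODEL, ]
  changes <- regional_change_series(annual_fut, base_means_models, region_map)
  data.table::fwrite(changes$series, outfile("changes_series.csv"))
  data.table::fwrite(changes$trends, outfile("changes_trends.csv"))
  record("changes", outfile(c("changes_series.csv", "changes_trends.csv")))

  # --- chi ------------------------------------------------------------------
  log_stage("chi", sprintf("composite index, %d selected model(s)",
                           length(selected)))
  chi_slices <- list(list(pm = pm_base, period = "baseline"))
  for (k in names(pm_fut)) {
    chi_slices[[length(chi_slices) + 1L]] <-
      list(pm = pm_fut[[k]], period = sub("^.*\\.", "", k))
  }
  chi_tabs <- lapply(chi_slices, function(sl) {
    compute_chi(sl$pm[sl$pm$model_id %in% selected, ],
                models = selected, period = sl$period)
  })
  chi_all <- do.call(rbind, chi_tabs)
  rownames(chi_all) <- NULL
  write_table(chi_all, outfile("chi.csv"), kind = "chi")
  record("chi", outfile("chi.csv"))

  # --- risk -----------------------------------------------------------------
  log_stage("risk", "population overlay (2050 <-> near future, 2090 <-> far future)")
  horizon_period <- c("2050" = "near_future", "2090" = "far_future")
  risk_rows <- list()
  for (scen in c("ssp245", "ssp585")) {
    for (hz in c(2050, 2090)) {
      chi_slice <- chi_all[chi_all$scenario == scen &
                             chi_all$period == horizon_period[[as.character(hz)]], ]
      for (ssp in names(spec$pop_multipliers)) {
        risk_rows[[paste(scen, ssp, hz)]] <-
          risk_table(chi_slice, population, ssp = ssp, horizon = hz)
      }
    }
  }
  risk_all <- do.call(rbind, risk_rows)
  rownames(risk_all) <- NULL
  write_table(risk_all, outfile("risk.csv"), kind = "risk")
  record("risk", outfile("risk.csv"))

  # --- coastal --------------------------------------------------------------
  log_stage("coastal", sprintf("classification with %.1f km buffer",
                               config$buffer_km))
  classification <- classify_coastal(spec$cities, coastline,
                                     buffer_km = config$buffer_km)
  data.table::fwrite(classification, outfile("coastal.csv"))
  cs <- coastal_summary(pm_base[pm_base$model_id %in% selected, ],
                        classification, index = "hwn",
                        diurnal_var = "tasmax")
  cs$outliers <- vapply(cs$outliers, function(v) paste(v, collapse = ";"),
                        character(1))
  data.table::fwrite(cs, outfile("coastal_summary.csv"))
  record("coastal", outfile(c("coastal.csv", "coastal_summary.csv")))

  # --- manifest -------------------------------------------------------------
  cfg_file <- outfile("config.yaml")
  writeLines(config_yaml(config), cfg_file)
  manifest <- list(
    package = "heatscape",
    version = as.character(packageVersion("heatscape")),
    config_hash = unname(tools::md5sum(cfg_file)),
    rng_seed = config$rng_seed,
    selected_models = as.list(selected),
    stages = unname(stages),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
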