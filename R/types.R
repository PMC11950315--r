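.REGIONS <- c("Northeast", "Southeast", "Midwest", "Southwest", "West")
.COAST_GROUPS <- c("WestCoast", "SouthCoast", "EastNorthCoast", "Inland", "Unclassified")
.SCENARIOS <- c("historical", "ssp245", "ssp585", "reference")
.DIURNAL_VARS <- c("tasmax", "tasmin")
.INDEX_NAMES <- c("hwn", "hwtd", "hwld", "hwmt", "hht")
.REFERENCE_MODEL <- "reference"

#' One city-model-scenario daily temperature record
#'
#' The pipeline's raw input: a gap-free daily series of one diurnal variable
#' (`tasmax` or `tasmin`) in degrees Celsius for one city, model, and scenario.
#'
#' @param city_id,model_id short tokens; `model_id = "reference"` is reserved
#'   for the observational reference dataset.
#' @param scenario one of `"historical"`, `"ssp245"`, `"ssp585"`, `"reference"`.
#' @param diurnal_var `"tasmax"` or `"tasmin"`.
#' @param year,doy integer vectors (parallel), gap-free daily steps under
#'   `calendar`.
#' @param value_c numeric temperatures in degrees Celsius.
#' @param calendar `"noleap"` or `"standard"`.
#' @return an object of class `daily_series`.
#' @export
daily_series <- function(city_id, model_id, scenario, diurnal_var,
                         year, doy, value_c, calendar = "noleap") {
  scenario <- match.arg(scenario, .SCENARIOS)
  diurnal_var <- match.arg(diurnal_var, .DIURNAL_VARS)
  calendar <- match.arg(calendar, .CALENDARS)
  year <- as.integer(year); doy <- as.integer(doy)
  if (length(value_c) != length(year) || length(doy) != length(year)) {
    stop("year, doy, value_c must have equal length")
  }
  validate_gap_free(year, doy, calendar,
                    what = paste0("series ", city_id, "/", model_id, "/",
                                  scenario, "/", diurnal_var))
  if (model_id != .REFERENCE_MODEL && anyNA(value_c)) {
    stop("model series ", city_id, "/", model_id,
         " contains missing values; only the reference series may")
  }
  structure(list(city_id = as.character(city_id),
                 model_id = as.character(model_id),
                 scenario = scenario, diurnal_var = diurnal_var,
                 calendar = calendar, year = year, doy = doy,
                 value_c = as.numeric(value_c)),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s / %s / %s / %s [%s]: %d days (%d-%d), %.1f..%.1f degC\n",
              x$city_id, x$model_id, x$scenario, x$diurnal_var, x$calendar,
              length(x$value_c), min(x$year), max(x$year),
              min(x$value_c, na.rm = TRUE), max(x$value_c, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.daily_series <- function(x) length(x$value_c)

series_key <- function(s) {
  paste(s$city_id, s$model_id, s$scenario, s$diurnal_var, sep = "|")
}

#' An inclusive analysis period
#'
#' @param label `"baseline"`, `"near_future"` or `"far_future"`.
#' @param start_year,end_year inclusive calendar years.
#' @return a `period_window` list.
#' @export
period_window <- function(label, start_year, end_year) {
  stopifnot(end_year >= start_year)
  structure(list(label = label, start_year = as.integer(start_year),
                 end_year = as.integer(end_year)),
            class = "period_window")
}

#' Default baseline / near-future / far-future windows
#'
#' Baseline 1985-2014, near future 2025-2054, far future 2065-2094.
#' @return named list of [period_window()] objects.
#' @export
default_windows <- function() {
  list(baseline = period_window("baseline", 1985, 2014),
       near_future = period_window("near_future", 2025, 2054),
       far_future = period_window("far_future", 2065, 2094))
}

#' Analysis configuration
#'
#' Collects every tunable of the pipeline: the percentile threshold, the
#' minimum event length, the period windows, the coastline buffer, the model
#' selection fraction, and the synthetic-generator seed.
#'
#' @param percentile_q exceedance quantile, in (0, 1); default 0.95.
#' @param min_event_days minimum run length in days for an event; default 3.
#' @param windows named list of the three [period_window()]s.
#' @param buffer_km coastal classification buffer, km; default 10.
#' @param selection_fraction model-selection threshold as a fraction of the
#'   maximum cumulative score; default 0.5 (the half-maximum rule).
#' @param rng_seed integer seed for every stochastic stage.
#' @param n_cities,n_models synthetic-ensemble dimensions.
#' @param write_daily write the raw simulated daily series as CSV in
#'   [run_all()] (large); default FALSE.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(percentile_q = 0.95, min_event_days = 3L,
                            windows = default_windows(), buffer_km = 10,
                            selection_fraction = 0.5, rng_seed = 1L,
                            n_cities = 10L, n_models = 5L,
                            write_daily = FALSE) {
  stopifnot(percentile_q > 0, percentile_q < 1, min_event_days >= 1,
            buffer_km > 0, selection_fraction > 0)
  structure(list(percentile_q = percentile_q,
                 min_event_days = as.integer(min_event_days),
                 windows = windows, buffer_km = buffer_km,
                 selection_fraction = selection_fraction,
                 rng_seed = as.integer(rng_seed),
                 n_cities = as.integer(n_cities),
                 n_models = as.integer(n_models),
                 write_daily = isTRUE(write_daily)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Scalar fields mirror [analysis_config()]; windows are given as
#' `windows: {baseline: [1985, 2014], near_future: [...], far_future: [...]}`.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("percentile_q", "min_event_days", "buffer_km",
                                  "selection_fraction", "rng_seed",
                                  "n_cities", "n_models", "write_daily"))]
  if (!is.null(y$windows)) {
    args$windows <- lapply(setNames(nm = names(y$windows)), function(lbl) {
      period_window(lbl, y$windows[[lbl]][1], y$windows[[lbl]][2])
    })
  }
  do.call(analysis_config, args)
}

# Canonical YAML text of a config (used for hashing into the run manifest).
config_yaml <- function(config) {
  yaml::as.yaml(list(
    percentile_q = config$percentile_q,
    min_event_days = config$min_event_days,
    windows = lapply(config$windows, function(w) c(w$start_year, w$end_year)),
    buffer_km = config$buffer_km,
    selection_fraction = config$selection_fraction,
    rng_seed = config$rng_seed, n_cities = config$n_cities,
    n_models = config$n_models, write_daily = config$write_daily))
}

#' Validate a city table
#'
#' @param cities data.frame with columns `city_id`, `name`, `region`, `lon`,
#'   `lat`, `coast_group`.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_city_table <- function(cities) {
  need <- c("city_id", "name", "region", "lon", "lat", "coast_group")
  miss <- setdiff(need, names(cities))
  if (length(miss)) stop("city table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cities$city_id)) {
    stop("duplicate city_id: ", cities$city_id[duplicated(cities$city_id)][1])
  }
  bad <- !cities$region %in% .REGIONS
  if (any(bad)) stop("unknown region '", cities$region[bad][1], "'")
  bad <- !cities$coast_group %in% .COAST_GROUPS
  if (any(bad)) stop("unknown coast_group '", cities$coast_group[bad][1], "'")
  if (any(abs(cities$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(cities$lon) > 180)) stop("longitude outside [-180, 180]")
  cities
}

# Deterministic sub-seed derivation: multiplicative hash over a tag string,
# kept below 2^31 so it is a valid R integer seed everywhere (the product
# stays under 2^53, so double arithmetic is exact).
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(tag)) h <- (h * 69069 + b) %% 2147483647
  as.integer(h)
}
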