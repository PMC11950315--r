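# Temporal change analysis: percentage changes relative to each model's own
# baseline mean, unweighted regional averaging of city values, multi-model
# median with interquartile spread, and ordinary least-squares trend fits.
# Aggregation order: city -> region average first (per model, per year),
# then the multi-model median/IQR across models, then per-year output.

#' Percentage change of a future value relative to a baseline mean
#'
#' `((future - baseline)/baseline) * 100`. Temperatures are in degrees
#' Celsius throughout; the result is not unit-invariant, so the Celsius
#' convention is part of the definition.
#'
#' @param future_value,baseline_mean numeric (vectorized).
#' @return percentage change; `NA` with a warning where the baseline mean
#'   is 0.
#' @export
percentage_change <- function(future_value, baseline_mean) {
  out <- (future_value - baseline_mean) / baseline_mean * 100
  zero <- !is.na(baseline_mean) & baseline_mean == 0
  if (any(zero)) {
    warning(sum(zero), " value(s) with zero baseline mean: change undefined")
    out[zero] <- NA_real_
  }
  out
}

#' Unweighted regional average of city values
#'
#' @param city_values data.frame `city_id, value` (one row per city; `value`
#'   may be `NA`, excluded with the divisor reduced).
#' @param region_map data.frame `city_id, region` covering every city.
#' @return data.frame `region, value, n_cities` (`n_cities` = cities that
#'   contributed, i.e. non-missing).
#' @export
regional_average <- function(city_values, region_map) {
  reg <- region_map$region[match(city_values$city_id, region_map$city_id)]
  if (anyNA(reg)) {
    stop("city not mapped to a region: ",
         city_values$city_id[is.na(reg)][1])
  }
  parts <- split(city_values$value, reg)
  out <- data.frame(
    region = names(parts),
    value = vapply(parts, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    n_cities = vapply(parts, function(v) sum(!is.na(v)), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Multi-model median and interquartile range
#'
#' Median and the 25th/75th percentiles across model values, under the same
#' linear-interpolation ("type 7") quantile convention as the detection
#' thresholds.
#'
#' @param model_values numeric vector, one value per model (length >= 1).
#' @return named numeric `c(median, q25, q75)`.
#' @export
ensemble_median_iqr <- function(model_values) {
  if (length(model_values) == 0L) stop("no model values")
  qs <- quantile(model_values, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
  c(median = unname(qs[2]), q25 = unname(qs[1]), q75 = unname(qs[3]))
}

#' Ordinary least-squares trend of value on year
#'
#' @param year,value numeric vectors (>= 3 distinct years).
#' @return list `slope` (value units per year), `r2` (squared correlation,
#'   `NA` when the values have zero variance), `n_years`.
#' @export
linear_trend <- function(year, value) {
  ok <- complete.cases(year, value)
  year <- year[ok]; value <- value[ok]
  if (length(unique(year)) < 3L) stop("need >= 3 distinct years")
  if (sd(value) == 0) {
    return(list(slope = 0, r2 = NA_real_, n_years = length(year)))
  }
  fit <- lm(value ~ year)
  list(slope = unname(coef(fit)[2]), r2 = cor(year, value)^2,
       n_years = length(year))
}

#' Regional ensemble change series and trends
#'
#' For every future-scenario annual index record, computes the percentage
#' change relative to the same model's own baseline period mean, averages
#' the city changes within each region (per model, per year), then takes the
#' multi-model median and interquartile range per region-year. A trend line
#' is fitted to each region's median series.
#'
#' @param annual future-period annual index records ([annual_indices()]
#'   rows) for the model ensemble (reference excluded).
#' @param baseline_means [period_mean_indices()] of the same models' own
#'   baseline (`scenario = "historical"`).
#' @param region_map data.frame `city_id, region`.
#' @return list of data.frames: `series` (`region, scenario, diurnal_var,
#'   index, year, median, q25, q75, n_models`) and `trends` (`region,
#'   scenario, diurnal_var, index, slope, r2, n_years`).
#' @export
regional_change_series <- function(annual, baseline_means, region_map) {
  base_key <- paste(baseline_means$city_id, baseline_means$model_id,
                    baseline_means$diurnal_var, baseline_means$index,
                    sep = "|")
  base_val <- setNames(baseline_means$mean, base_key)
  rows <- list()
  for (ix in .INDEX_NAMES) {
    k <- paste(annual$city_id, annual$model_id, annual$diurnal_var, ix,
               sep = "|")
    base <- unname(base_val[k])
    fut <- annual[[ix]]
    pct <- suppressWarnings((fut - base) / base * 100)
    pct[!is.na(base) & base == 0] <- NA_real_
    rows[[ix]] <- data.frame(
      city_id = annual$city_id, model_id = annual$model_id,
      scenario = annual$scenario, diurnal_var = annual$diurnal_var,
      index = ix, year = annual$year, pct_change = pct,
      stringsAsFactors = FALSE)
  }
  ch <- do.call(rbind, rows)
  ch$region <- region_map$region[match(ch$city_id, region_map$city_id)]
  if (anyNA(ch$region)) stop("city without region: ",
                             ch$city_id[is.na(ch$region)][1])

  # region average per (model, scenario, var, index, year)
  reg <- aggregate(pct_change ~ region + model_id + scenario + diurnal_var +
                     index + year, data = ch, FUN = mean, na.rm = TRUE,
                   na.action = stats::na.pass)

  # ensemble median/IQR across models
  gkey <- interaction(reg$region, reg$scenario, reg$diurnal_var, reg$index,
                      reg$year, drop = TRUE)
  parts <- split(reg, gkey)
  series <- do.call(rbind, lapply(parts, function(g) {
    ok <- !is.na(g$pct_change)
    m <- if (any(ok)) ensemble_median_iqr(g$pct_change[ok]) else
      c(median = NA_real_, q25 = NA_real_, q75 = NA_real_)
    data.frame(region = g$region[1], scenario = g$scenario[1],
               diurnal_var = g$diurnal_var[1], index = g$index[1],
               year = g$year[1], median = m[["median"]], q25 = m[["q25"]],
               q75 = m[["q75"]], n_models = sum(ok),
               stringsAsFactors = FALSE)
  }))
  series <- series[order(series$region, series$scenario, series$diurnal_var,
                         series$index, series$year), ]
  rownames(series) <- NULL

  tkey <- interaction(series$region, series$scenario, series$diurnal_var,
                      series$index, drop = TRUE)
  trends <- do.call(rbind, lapply(split(series, tkey), function(g) {
    ok <- !is.na(g$median)
    if (sum(ok) < 3L) {
      tf <- list(slope = NA_real_, r2 = NA_real_, n_years = sum(ok))
    } else {
      tf <- linear_trend(g$year[ok], g$median[ok])
    }
    data.frame(region = g$region[1], scenario = g$scenario[1],
               diurnal_var = g$diurnal_var[1], index = g$index[1],
               slope = tf$slope, r2 = tf$r2, n_years = tf$n_years,
               stringsAsFactors = FALSE)
  }))
  rownames(trends) <- NULL
  list(series = series, trends = trends)
}
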