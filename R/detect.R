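# Heatwave detection and annual indices. A heatwave is a maximal run of at
# least `min_event_days` consecutive days whose temperature is strictly above
# the city's fixed baseline-period percentile threshold. Five annual indices
# follow: HWN (events per year, attributed to the start year), HWTD (heatwave
# days per year, each day attributed to its own year), HWLD (longest
# within-year consecutive stretch of heatwave days), HWMT (mean temperature
# over the year's heatwave days), HHT (hottest heatwave-day temperature).
# HWMT/HHT are missing (NA), never zero, in event-free years.

#' Baseline percentile threshold for one series
#'
#' Pools every day of the baseline window (no day-of-year windowing) and
#' takes the empirical quantile under the linear-interpolation ("type 7")
#' convention. Thresholds are computed once on the baseline and held constant
#' for future periods.
#'
#' @param series a [daily_series()] covering `window` completely.
#' @param window a [period_window()] (typically the 1985-2014 baseline).
#' @param q quantile, in (0, 1); default 0.95.
#' @return object of class `hw_threshold`: list with `city_id`, `diurnal_var`,
#'   `q`, `value` (degC), `window`.
#' @export
baseline_threshold <- function(series, window, q = 0.95) {
  stopifnot(q > 0, q < 1)
  have <- unique(series$year)
  want <- window$start_year:window$end_year
  miss <- setdiff(want, have)
  if (length(miss)) {
    stop("series does not cover the window: missing year(s) ",
         paste(head(miss, 5), collapse = ", "))
  }
  v <- series$value_c[series$year %in% want]
  structure(list(city_id = series$city_id, diurnal_var = series$diurnal_var,
                 q = q, value = unname(quantile(v, q, type = 7, na.rm = TRUE)),
                 window = window),
            class = "hw_threshold")
}

#' Detect heatwave events as maximal exceedance runs
#'
#' Events are exactly the maximal runs of strictly threshold-exceeding days
#' with length at least `min_event_days`, in chronological order,
#' non-overlapping. Detection runs on the continuous series; events may
#' straddle year boundaries.
#'
#' @param series a [daily_series()].
#' @param threshold an `hw_threshold` from [baseline_threshold()] for the
#'   same city and diurnal variable.
#' @param min_event_days minimum run length; default 3.
#' @return data.frame with one row per event: `city_id, model_id, scenario,
#'   diurnal_var, start_year, start_doy, end_year, end_doy, start_idx,
#'   duration`, plus a list column `temps` of the event's daily temperatures.
#' @export
detect_events <- function(series, threshold, min_event_days = 3L) {
  if (!identical(threshold$city_id, series$city_id) ||
      !identical(threshold$diurnal_var, series$diurnal_var)) {
    stop("threshold is for ", threshold$city_id, "/", threshold$diurnal_var,
         ", series is ", series$city_id, "/", series$diurnal_var)
  }
  stopifnot(min_event_days >= 1)
  exceed <- !is.na(series$value_c) & series$value_c > threshold$value
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_event_days
  starts <- starts[keep]; ends <- ends[keep]
  ev <- data.frame(
    city_id = rep(series$city_id, length(starts)),
    model_id = rep(series$model_id, length(starts)),
    scenario = rep(series$scenario, length(starts)),
    diurnal_var = rep(series$diurnal_var, length(starts)),
    start_year = series$year[starts], start_doy = series$doy[starts],
    end_year = series$year[ends], end_doy = series$doy[ends],
    start_idx = starts, duration = ends - starts + 1L,
    stringsAsFactors = FALSE)
  ev$temps <- lapply(seq_along(starts), function(i) {
    series$value_c[starts[i]:ends[i]]
  })
  ev
}

#' Annual heatwave indices from detected events
#'
#' @param events output of [detect_events()] on `series`.
#' @param series the same [daily_series()].
#' @param years integer vector of years to summarize (each must be covered by
#'   the series); default all years of the series.
#' @return data.frame with columns `city_id, model_id, scenario, diurnal_var,
#'   year, hwn, hwtd, hwld, hwmt, hht`; `hwmt`/`hht` are `NA` when
#'   `hwtd == 0`.
#' @export
annual_indices <- function(events, series, years = sort(unique(series$year))) {
  bad <- setdiff(years, series$year)
  if (length(bad)) stop("year(s) outside series coverage: ",
                        paste(head(bad, 5), collapse = ", "))
  n <- length(series)
  hw_day <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    hw_day[events$start_idx[i]:(events$start_idx[i] + events$duration[i] - 1L)] <- TRUE
  }
  out <- lapply(years, function(y) {
    in_year <- series$year == y
    days <- hw_day & in_year
    hwtd <- sum(days)
    hwn <- if (nrow(events)) sum(events$start_year == y) else 0L
    hwld <- if (hwtd == 0L) 0L else {
      r <- rle(days[in_year])
      max(r$lengths[r$values])
    }
    temps <- series$value_c[days]
    data.frame(city_id = series$city_id, model_id = series$model_id,
               scenario = series$scenario, diurnal_var = series$diurnal_var,
               year = y, hwn = as.integer(hwn), hwtd = as.integer(hwtd),
               hwld = as.integer(hwld),
               hwmt = if (hwtd) mean(temps) else NA_real_,
               hht = if (hwtd) max(temps) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annual indices for a whole daily collection
#'
#' Computes each series' fixed baseline threshold from `baseline_source`
#' (the same model's own baseline-scenario series for the matching city and
#' variable) and applies it to every series in `collection`.
#'
#' @param collection list of [daily_series()] to index.
#' @param baseline_source list of [daily_series()] providing the baseline
#'   days (may be the same list when indexing the baseline itself).
#' @param baseline_window the [period_window()] thresholds are computed on.
#' @param q percentile, default 0.95.
#' @param min_event_days default 3.
#' @return data.frame of stacked [annual_indices()] records.
#' @export
compute_annual_indices <- function(collection, baseline_source,
                                   baseline_window, q = 0.95,
                                   min_event_days = 3L) {
  thr_key <- vapply(baseline_source, function(s) {
    paste(s$city_id, s$model_id, s$diurnal_var, sep = "|")
  }, character(1))
  thresholds <- lapply(baseline_source, baseline_threshold,
                       window = baseline_window, q = q)
  names(thresholds) <- thr_key
  rows <- lapply(collection, function(s) {
    key <- paste(s$city_id, s$model_id, s$diurnal_var, sep = "|")
    thr <- thresholds[[key]]
    if (is.null(thr)) stop("no baseline series for ", key)
    ev <- detect_events(s, thr, min_event_days)
    annual_indices(ev, s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Period means of the annual indices
#'
#' Arithmetic mean of each index over the window's years, per city, model,
#' scenario, and diurnal variable. The intensity indices (`hwmt`, `hht`)
#' average over years with events only; the number of contributing years is
#' recorded in `n_years`.
#'
#' @param records data.frame of [annual_indices()] rows.
#' @param window a [period_window()]; every window year must be present for
#'   each group.
#' @return data.frame in long form: `city_id, model_id, scenario,
#'   diurnal_var, index, mean, n_years`.
#' @export
period_mean_indices <- function(records, window) {
  if (nrow(records) == 0L) stop("empty index record set")
  want <- window$start_year:window$end_year
  recs <- records[records$year %in% want, ]
  if (nrow(recs) == 0L) stop("no records inside window ", window$label)
  key <- interaction(recs$city_id, recs$model_id, recs$scenario,
                     recs$diurnal_var, drop = TRUE)
  parts <- split(recs, key)
  rows <- lapply(parts, function(g) {
    miss <- setdiff(want, g$year)
    if (length(miss)) {
      stop("group ", g$city_id[1], "/", g$model_id[1],
           " missing window year(s) ", paste(head(miss, 5), collapse = ", "))
    }
    long <- lapply(.INDEX_NAMES, function(ix) {
      v <- g[[ix]]
      ok <- !is.na(v)
      data.frame(city_id = g$city_id[1], model_id = g$model_id[1],
                 scenario = g$scenario[1], diurnal_var = g$diurnal_var[1],
                 index = ix,
                 mean = if (any(ok)) mean(v[ok]) else NA_real_,
                 n_years = sum(ok), stringsAsFactors = FALSE)
    })
    do.call(rbind, long)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
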