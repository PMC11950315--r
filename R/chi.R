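# Composite heatwave index (CHI). For one period, scenario, and model: each
# of the five period-mean indices is min-max normalized across cities within
# one diurnal dataset; the five normalized metrics are averaged per dataset;
# the daytime and nighttime composites are averaged; and the combined values
# are min-max re-normalized across cities so the hottest city scores exactly
# 1 and the coolest exactly 0.

#' Min-max normalization across cities
#'
#' `(x - min)/(max - min)`. When every city is equal (degenerate spread) all
#' cities map to 0 — a metric with no spread raises no city's hazard — and
#' the result carries `attr(, "degenerate") = TRUE`.
#'
#' @param values named numeric vector (city -> raw metric), length >= 2.
#'   `NA`s are preserved.
#' @return numeric in `[0, 1]`, same names.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L) stop("min-max normalization needs >= 2 cities")
  lo <- min(values, na.rm = TRUE)
  hi <- max(values, na.rm = TRUE)
  if (!is.finite(lo) || !is.finite(hi)) stop("all values missing")
  if (hi == lo) {
    out <- ifelse(is.na(values), NA_real_, 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - lo) / (hi - lo)
}

#' Composite of the five normalized metrics for one dataset
#'
#' Arithmetic mean of the five normalized metrics. A missing intensity
#' component (an event-free city has no HWMT/HHT) is imputed as 0 before
#' averaging: such a city carries the least possible intensity burden.
#'
#' @param x numeric matrix or data.frame, cities x 5 normalized metrics.
#' @return numeric vector of per-city composites.
#' @export
composite_per_dataset <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 5L) stop("expected exactly 5 normalized metrics")
  if (any(rowSums(!is.na(x)) == 0L)) stop("a city has all five metrics missing")
  x[is.na(x)] <- 0
  rowMeans(x)
}

#' Combine daytime and nighttime composites
#'
#' @param c_day,c_night per-city composites in `[0, 1]`.
#' @return `(c_day + c_night)/2`.
#' @export
combine_day_night <- function(c_day, c_night) {
  (c_day + c_night) / 2
}

#' Final min-max re-normalization of the combined CHI
#'
#' @param chi_combined per-city combined CHI.
#' @return per-city final CHI in `[0, 1]`; the hottest city maps to exactly
#'   1, the coolest to exactly 0 (all-equal input maps to 0, flagged via the
#'   `degenerate` attribute).
#' @export
final_normalize <- function(chi_combined) {
  minmax_normalize(chi_combined)
}

#' Compute CHI for one period and scenario
#'
#' Runs the full normalization chain per model across cities, then forms the
#' ensemble CHI as the per-city median of the per-model final CHI values
#' across the given models, re-normalized across cities (`model_id =
#' "ensemble"`).
#'
#' @param period_means long table from [period_mean_indices()] covering both
#'   diurnal variables for one scenario and period.
#' @param models character vector of model ids to include (e.g. the selected
#'   models); default all non-reference models present.
#' @param period label stored in the output (`"baseline"`, `"near_future"`,
#'   `"far_future"`).
#' @return data.frame `city_id, model_id, scenario, period, c_day, c_night,
#'   chi_combined, chi_final`, including the `"ensemble"` rows.
#' @export
compute_chi <- function(period_means, models = NULL, period = "baseline") {
  pm <- period_means
  if (is.null(models)) {
    models <- setdiff(unique(pm$model_id), .REFERENCE_MODEL)
  }
  pm <- pm[pm$model_id %in% models, ]
  if (nrow(pm) == 0L) stop("no records for the requested models")
  scenario <- unique(pm$scenario)
  if (length(scenario) != 1L) stop("period_means spans several scenarios")
  cities <- sort(unique(pm$city_id))
  if (length(cities) < 2L) stop("CHI needs >= 2 cities")

  per_model <- lapply(sort(models), function(m) {
    g <- pm[pm$model_id == m, ]
    comps <- lapply(.DIURNAL_VARS, function(v) {
      xs <- vapply(.INDEX_NAMES, function(ix) {
        sel <- g$diurnal_var == v & g$index == ix
        raw <- setNames(g$mean[sel], g$city_id[sel])
        raw <- raw[cities]
        as.numeric(minmax_normalize(raw))
      }, numeric(length(cities)))
      composite_per_dataset(xs)
    })
    c_day <- comps[[which(.DIURNAL_VARS == "tasmax")]]
    c_night <- comps[[which(.DIURNAL_VARS == "tasmin")]]
    chi_combined <- combine_day_night(c_day, c_night)
    data.frame(city_id = cities, model_id = m, scenario = scenario,
               period = period, c_day = c_day, c_night = c_night,
               chi_combined = chi_combined,
               chi_final = as.numeric(final_normalize(chi_combined)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_model)

  # ensemble: per-city median of the per-model final CHI, re-normalized
  med <- tapply(out$chi_final, out$city_id, median)
  med <- med[cities]
  ens <- data.frame(city_id = cities, model_id = "ensemble",
                    scenario = scenario, period = period,
                    c_day = NA_real_, c_night = NA_real_,
                    chi_combined = as.numeric(med),
                    chi_final = as.numeric(final_normalize(as.numeric(med))),
                    stringsAsFactors = FALSE)
  out <- rbind(out, ens)
  rownames(out) <- NULL
  out
}
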