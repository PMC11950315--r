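# Coastal vs. inland classification and group summaries. A city is coastal
# when its representative point lies within buffer_km (default 10 km,
# boundary inclusive) great-circle distance of the coastline polyline.
# Segments are treated as geodesic chords; the distance to a segment is the
# cross-track distance when the perpendicular foot falls inside the segment,
# otherwise the distance to the nearer endpoint. Radius 6371 km throughout.

.EARTH_R <- 6371000  # metres

# Great-circle distance (km) from one lon/lat point to a polyline part.
point_to_polyline_km <- function(lon, lat, line) {
  p <- cbind(lon, lat)
  n <- nrow(line)
  if (n == 1L) {
    return(geosphere::distHaversine(p, line[1, ], r = .EARTH_R) / 1000)
  }
  a <- line[-n, , drop = FALSE]
  b <- line[-1, , drop = FALSE]
  dv <- geosphere::distHaversine(p, line, r = .EARTH_R)  # to each vertex
  best <- min(dv)
  seg_len <- geosphere::distHaversine(a, b, r = .EARTH_R)
  at <- geosphere::alongTrackDistance(a, b, p, r = .EARTH_R)
  xt <- abs(geosphere::dist2gc(a, b, p, r = .EARTH_R))
  inside <- is.finite(at) & at > 0 & at < seg_len & seg_len > 0
  if (any(inside)) best <- min(best, xt[inside])
  best / 1000
}

#' Classify cities as coastal or inland
#'
#' @param cities city table (see [validate_city_table()]); `coast_group`
#'   supplies the coastal grouping for cities classified coastal.
#' @param coastline list of lon/lat polyline matrices (from
#'   [read_coastline()] or [generate_coastline()]).
#' @param buffer_km classification buffer; a city at exactly `buffer_km` is
#'   coastal (inclusive). Default 10.
#' @return data.frame `city_id, distance_km, coastal, coast_group`; inland
#'   cities get `coast_group = "Inland"`.
#' @export
classify_coastal <- function(cities, coastline, buffer_km = 10) {
  if (!length(coastline)) stop("empty coastline")
  cities <- validate_city_table(cities)
  dist_km <- vapply(seq_len(nrow(cities)), function(i) {
    min(vapply(coastline, function(line) {
      point_to_polyline_km(cities$lon[i], cities$lat[i], line)
    }, numeric(1)))
  }, numeric(1))
  coastal <- dist_km <= buffer_km
  grp <- ifelse(coastal, cities$coast_group, "Inland")
  grp[coastal & grp == "Inland"] <- "Unclassified"
  data.frame(city_id = cities$city_id, distance_km = dist_km,
             coastal = coastal, coast_group = grp, stringsAsFactors = FALSE)
}

#' Box-plot statistics per group
#'
#' Quartiles under the linear-interpolation ("type 7") convention; whiskers
#' extend to the most extreme observations within 1.5 IQR of the box edges
#' (Tukey rule); observations beyond the whiskers are outliers.
#'
#' @param values numeric vector.
#' @param groups grouping vector, parallel to `values`.
#' @return data.frame `group, n, median, q25, q75, whisker_low,
#'   whisker_high` with a list column `outliers`.
#' @export
group_box_stats <- function(values, groups) {
  parts <- split(values, groups)
  if (any(vapply(parts, length, integer(1)) == 0L)) stop("empty group")
  rows <- lapply(names(parts), function(g) {
    v <- parts[[g]][!is.na(parts[[g]])]
    if (!length(v)) stop("group '", g, "' has no non-missing values")
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
    iqr <- qs[3] - qs[1]
    lo_fence <- qs[1] - 1.5 * iqr
    hi_fence <- qs[3] + 1.5 * iqr
    inside <- v >= lo_fence & v <= hi_fence
    out <- data.frame(group = g, n = length(v), median = unname(qs[2]),
                      q25 = unname(qs[1]), q75 = unname(qs[3]),
                      whisker_low = min(v[inside]),
                      whisker_high = max(v[inside]),
                      stringsAsFactors = FALSE)
    out$outliers <- list(sort(v[!inside]))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Heatwave summaries by coastal group
#'
#' Box-plot statistics of a period-mean index across the cities of each
#' coastal group, per model/scenario/diurnal combination collapsed by the
#' ensemble mean per city first.
#'
#' @param period_means long table from [period_mean_indices()].
#' @param classification output of [classify_coastal()].
#' @param index one of `hwn, hwtd, hwld, hwmt, hht`.
#' @param diurnal_var `"tasmax"` or `"tasmin"`.
#' @return [group_box_stats()] table over coast groups, where each
#'   observation is one city's across-model mean of the period-mean index.
#' @export
coastal_summary <- function(period_means, classification, index = "hwn",
                            diurnal_var = "tasmax") {
  index <- match.arg(index, .INDEX_NAMES)
  diurnal_var <- match.arg(diurnal_var, .DIURNAL_VARS)
  pm <- period_means[period_means$index == index &
                       period_means$diurnal_var == diurnal_var &
                       period_means$model_id != .REFERENCE_MODEL, ]
  if (nrow(pm) == 0L) stop("no records for ", index, "/", diurnal_var)
  city_val <- tapply(pm$mean, pm$city_id, mean, na.rm = TRUE)
  grp <- classification$coast_group[match(names(city_val),
                                          classification$city_id)]
  if (anyNA(grp)) stop("city missing from classification: ",
                       names(city_val)[is.na(grp)][1])
  group_box_stats(as.numeric(city_val), grp)
}
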