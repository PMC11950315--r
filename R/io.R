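# Readers and writers. All tabular IO is UTF-8 CSV with "." decimal; the
# long daily format is: city_id, model_id, scenario, diurnal_var, date,
# value_c. Numeric columns round-trip at the precision written.

.TABLE_KINDS <- list(
  indices = c("city_id", "model_id", "scenario", "diurnal_var", "year",
              "hwn", "hwtd", "hwld", "hwmt", "hht"),
  chi = c("city_id", "model_id", "scenario", "period",
          "c_day", "c_night", "chi_combined", "chi_final"),
  risk = c("city_id", "scenario", "ssp", "horizon", "pop", "pop_change_pct",
           "pop_norm", "pop_change_norm", "chi_final", "risk_abs", "risk_change"),
  scores = c("model_id", "cumulative_score", "threshold", "selected")
)

#' Read daily temperature series from file
#'
#' The supported dialect is `csv_long`: a UTF-8 CSV with header
#' `city_id, model_id, scenario, diurnal_var, date, value_c` (dates ISO-8601,
#' temperatures in degrees Celsius). Each (city, model, scenario, variable)
#' group must form a gap-free daily calendar; gaps or duplicates are rejected
#' naming the first offending date. The `netcdf_cf` dialect token is part of
#' the interface but not available in this build.
#'
#' @param path input file.
#' @param dialect `"csv_long"` or `"netcdf_cf"`.
#' @param calendar calendar the dates are validated against.
#' @return list of [daily_series()] objects (a "daily collection").
#' @export
read_daily_series <- function(path, dialect = c("csv_long", "netcdf_cf"),
                              calendar = "noleap") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "netcdf_cf") {
    stop("dialect 'netcdf_cf' is not supported in this build; ",
         "export the data as csv_long")
  }
  df <- data.table::fread(path, colClasses = list(character = "date"),
                          data.table = FALSE)
  need <- c("city_id", "model_id", "scenario", "diurnal_var", "date", "value_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("csv_long missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- !df$diurnal_var %in% .DIURNAL_VARS
  if (any(bad)) stop("unknown diurnal_var token '", df$diurnal_var[bad][1], "'")
  parts <- split(df, paste(df$city_id, df$model_id, df$scenario,
                           df$diurnal_var, sep = "|"))
  out <- lapply(parts, function(g) {
    yd <- parse_dates(g$date, calendar)
    o <- order(yd$year, yd$doy)
    daily_series(g$city_id[1], g$model_id[1], g$scenario[1], g$diurnal_var[1],
                 yd$year[o], yd$doy[o], g$value_c[o], calendar = calendar)
  })
  unname(out)
}

#' Write a daily collection to the long CSV format
#'
#' @param series list of [daily_series()].
#' @param path output CSV.
#' @export
write_daily_series <- function(series, path) {
  rows <- lapply(series, function(s) {
    cal <- daily_calendar(min(s$year), max(s$year), s$calendar)
    date <- cal$date[match(paste(s$year, s$doy), paste(cal$year, cal$doy))]
    data.frame(city_id = s$city_id, model_id = s$model_id,
               scenario = s$scenario, diurnal_var = s$diurnal_var,
               date = date, value_c = s$value_c, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' Rank cities by 2020 population and keep the top k
#'
#' Ties are broken by `city_id` ascending.
#'
#' @param population_table data.frame with columns `city_id` and `population`
#'   (2020 totals).
#' @param k number of cities to keep.
#' @return character vector of `city_id`, population-descending.
#' @export
select_top_cities <- function(population_table, k) {
  stopifnot(all(c("city_id", "population") %in% names(population_table)))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(population_table)) stop("k exceeds number of cities")
  if (any(population_table$population < 0)) stop("negative population")
  o <- order(-population_table$population, population_table$city_id)
  head(population_table$city_id[o], k)
}

#' Write / read a pipeline result table
#'
#' Each table kind (`indices`, `chi`, `risk`, `scores`) has a fixed,
#' documented column order; writing rejects records whose columns do not
#' match the kind, and reading restores the same types so a write/read
#' round trip is value-identical at the precision written.
#'
#' @param records data.frame of one kind.
#' @param path CSV path.
#' @param kind one of `names(.TABLE_KINDS)`.
#' @param allow_empty write a header-only file for an empty record set.
#' @export
write_table <- function(records, path, kind = c("indices", "chi", "risk", "scores"),
                        allow_empty = FALSE) {
  kind <- match.arg(kind)
  cols <- .TABLE_KINDS[[kind]]
  if (nrow(records) == 0L && !allow_empty) {
    stop("empty record set (pass allow_empty = TRUE for a header-only file)")
  }
  miss <- setdiff(cols, names(records))
  if (length(miss)) {
    stop("records do not match kind '", kind, "': missing column(s) ",
         paste(miss, collapse = ", "))
  }
  data.table::fwrite(records[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, kind = c("indices", "chi", "risk", "scores")) {
  kind <- match.arg(kind)
  df <- data.table::fread(path, data.table = FALSE)
  cols <- .TABLE_KINDS[[kind]]
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("file is not a '", kind, "' table: missing ",
                         paste(miss, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Read a city table CSV
#'
#' Columns: `city_id, name, region, lon, lat, coast_group`.
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_city_table <- function(path) {
  validate_city_table(data.table::fread(path, data.table = FALSE))
}

#' Read a coastline from GeoJSON
#'
#' Accepts a GeoJSON `LineString`, `MultiLineString`, or a
#' Feature/FeatureCollection wrapping them.
#'
#' @param path GeoJSON file.
#' @return list of numeric matrices (columns lon, lat), one per polyline part.
#' @export
read_coastline <- function(path) {
  g <- jsonlite::read_json(path)
  parts <- extract_lines(g)
  if (!length(parts)) stop("no LineString/MultiLineString geometry found in ", path)
  parts
}

extract_lines <- function(g) {
  if (is.null(g$type)) return(list())
  switch(g$type,
    FeatureCollection = do.call(c, lapply(g$features, extract_lines)),
    Feature = extract_lines(g$geometry),
    LineString = list(coords_matrix(g$coordinates)),
    MultiLineString = lapply(g$coordinates, coords_matrix),
    list())
}

coords_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("lon", "lat")
  m
}

#' Write a coastline polyline as GeoJSON
#'
#' @param lines list of lon/lat matrices (as returned by [read_coastline()]).
#' @param path output file.
#' @export
write_coastline <- function(lines, path) {
  geom <- if (length(lines) == 1L) {
    list(type = "LineString",
         coordinates = lapply(seq_len(nrow(lines[[1]])),
                              function(i) as.numeric(lines[[1]][i, ])))
  } else {
    list(type = "MultiLineString",
         coordinates = lapply(lines, function(m) {
           lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
         }))
  }
  jsonlite::write_json(list(type = "Feature", properties = NULL, geometry = geom),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
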