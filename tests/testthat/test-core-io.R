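test_that("to_celsius converts Kelvin exactly and leaves Celsius alone", {
  expect_equal(to_celsius(273.15, "K"), 0)
  expect_equal(to_celsius(300, "K"), 26.85)
  expect_equal(to_celsius(25, "C"), 25)
  expect_equal(to_celsius(to_celsius(c(-5, 0, 40), "C"), "C"), c(-5, 0, 40))
  expect_length(to_celsius(1:7, "K"), 7)
  expect_error(to_celsius(1, "F"), "unknown temperature unit.*F")
})

test_that("daily calendars are gap-free and calendar-aware", {
  cal <- daily_calendar(2000, 2001, "noleap")
  expect_equal(nrow(cal), 730)
  expect_false(any(grepl("02-29", cal$date)))
  cal_std <- daily_calendar(2000, 2000, "standard")
  expect_equal(nrow(cal_std), 366)  # 2000 is a leap year
  expect_true("2000-02-29" %in% cal_std$date)
})

test_that("read_daily_series parses csv_long into one series per key tuple", {
  cal <- daily_calendar(2000, 2000, "noleap")[1:10, ]
  rows <- expand.grid(city_id = c("A", "B"), diurnal_var = c("tasmax", "tasmin"),
                      stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    data.frame(city_id = rows$city_id[i], model_id = "M1",
               scenario = "historical", diurnal_var = rows$diurnal_var[i],
               date = cal$date, value_c = seq_len(10) + i)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  got <- read_daily_series(path)
  expect_length(got, 4)  # 2 cities x 2 diurnal variables
  keys <- sort(vapply(got, function(s) paste(s$city_id, s$diurnal_var),
                      character(1)))
  expect_equal(keys, c("A tasmax", "A tasmin", "B tasmax", "B tasmin"))

  # header-only file -> empty collection
  writeLines("city_id,model_id,scenario,diurnal_var,date,value_c", path)
  expect_length(read_daily_series(path), 0)

  # a missing calendar day is rejected naming the gap
  gap <- df[df$city_id == "A" & df$diurnal_var == "tasmax", ][-5, ]
  write.csv(gap, path, row.names = FALSE)
  expect_error(read_daily_series(path), "gap")

  # unknown diurnal variable token is rejected
  bad <- df; bad$diurnal_var[1] <- "tmean"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_daily_series(path), "diurnal_var.*tmean")

  expect_error(read_daily_series(path, dialect = "netcdf_cf"), "not supported")
})

test_that("daily series round-trips through the long CSV format", {
  s <- make_series(round(rnorm(30, 20, 5), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_series(list(s), path)
  back <- read_daily_series(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$value_c, s$value_c)
  expect_equal(back[[1]]$year, s$year)
  expect_equal(back[[1]]$doy, s$doy)
})

test_that("select_top_cities sorts by population with documented tie rule", {
  tab <- data.frame(city_id = c("A", "B", "C"), population = c(100, 300, 200))
  expect_equal(select_top_cities(tab, 2), c("B", "C"))
  expect_equal(select_top_cities(tab, 3), c("B", "C", "A"))
  tie <- data.frame(city_id = c("B", "A"), population = c(100, 100))
  expect_equal(select_top_cities(tie, 1), "A")
  expect_error(select_top_cities(tab, 0), "positive")
  expect_error(select_top_cities(tab, 4), "exceeds")
  # permutation invariance of the input table
  perm <- tab[c(3, 1, 2), ]
  expect_equal(select_top_cities(perm, 2), select_top_cities(tab, 2))
})

test_that("result tables round-trip by kind and reject mismatched records", {
  idx <- data.frame(city_id = "A", model_id = "M1", scenario = "historical",
                    diurnal_var = "tasmax", year = 2000L, hwn = 2L,
                    hwtd = 7L, hwld = 4L, hwmt = 32.0, hht = 34.0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(idx, path, kind = "indices")
  expect_equal(read_table(path, kind = "indices"), idx,
               ignore_attr = TRUE)
  # empty set needs the explicit flag, then yields a header-only file
  expect_error(write_table(idx[0, ], path, kind = "indices"), "empty")
  write_table(idx[0, ], path, kind = "indices", allow_empty = TRUE)
  expect_equal(nrow(read_table(path, kind = "indices")), 0)
  # wrong-kind records are rejected
  expect_error(write_table(idx, path, kind = "scores"), "missing column")
})

test_that("coastline GeoJSON round-trips through reader and writer", {
  lines <- list(cbind(lon = c(-122, -122), lat = c(32, 48)),
                cbind(lon = c(-97, -82), lat = c(27, 27)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_coastline(lines, path)
  back <- read_coastline(path)
  expect_length(back, 2)
  expect_equal(back[[1]][, "lat"], c(32, 48), ignore_attr = TRUE)
  expect_equal(back[[2]][, "lon"], c(-97, -82), ignore_attr = TRUE)
})

test_that("city table validation enforces the closed region set and ranges", {
  ok <- data.frame(city_id = c("A", "B"), name = c("a", "b"),
                   region = c("West", "Midwest"), lon = c(-120, -90),
                   lat = c(40, 42), coast_group = c("WestCoast", "Inland"))
  expect_silent(validate_city_table(ok))
  bad <- ok; bad$region[1] <- "Plains"
  expect_error(validate_city_table(bad), "unknown region")
  bad <- ok; bad$lat[1] <- 95
  expect_error(validate_city_table(bad), "latitude")
  bad <- ok; bad$city_id[2] <- "A"
  expect_error(validate_city_table(bad), "duplicate")
})

test_that("configuration round-trips through YAML", {
  cfg <- analysis_config(percentile_q = 0.9, min_event_days = 2,
                         rng_seed = 42, n_cities = 4, n_models = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(heatscape:::config_yaml(cfg), path)
  back <- read_config(path)
  expect_equal(back$percentile_q, 0.9)
  expect_equal(back$min_event_days, 2L)
  expect_equal(back$windows$baseline$start_year, 1985L)
  expect_equal(back$rng_seed, 42L)
})
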