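# Shared builders and independent oracles for the suite.

# A gap-free daily series starting 1 Jan of `year` with the given values.
make_series <- function(values, year = 2000, city_id = "X", model_id = "M",
                        scenario = "historical", diurnal_var = "tasmax") {
  n <- length(values)
  years <- year + (seq_len(n) - 1L) %/% 365L
  doys <- (seq_len(n) - 1L) %% 365L + 1L
  daily_series(city_id, model_id, scenario, diurnal_var,
               years, doys, values, calendar = "noleap")
}

# A threshold object without going through baseline_threshold.
make_threshold <- function(value, city_id = "X", diurnal_var = "tasmax",
                           q = 0.95) {
  structure(list(city_id = city_id, diurnal_var = diurnal_var, q = q,
                 value = value,
                 window = period_window("baseline", 2000, 2000)),
            class = "hw_threshold")
}

# Exhaustive maximal-run oracle: every (start, end) window of strictly
# exceeding days that cannot be extended either way and is long enough.
brute_force_events <- function(values, threshold, min_days) {
  exceed <- values > threshold
  n <- length(values)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(exceed[s:e]) &&
          (s == 1 || !exceed[s - 1]) &&
          (e == n || !exceed[e + 1]) &&
          (e - s + 1) >= min_days) {
        out[[length(out) + 1L]] <- c(start = s, end = e)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}
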