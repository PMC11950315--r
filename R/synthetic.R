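# Synthetic multi-city, multi-model daily temperature ensembles and SSP-style
# population trajectories. The generator emulates the statistical structure
# the downstream analysis assumes: a seasonal cycle with AR(1) day-to-day
# autocorrelation, per-scenario linear warming, per-model additive biases
# around a shared "truth", additive warm-season heat-dome episodes, and
# per-SSP population multipliers. It makes no claim of meteorological realism
# beyond that structure. All randomness flows through R's Mersenne-Twister
# generator, seeded per series from the spec seed, so fixed seeds give
# bit-identical ensembles.

#' Specification of a synthetic heatwave ensemble
#'
#' @param n_cities,n_models ensemble dimensions.
#' @param seed master RNG seed; every generated object derives its own
#'   sub-seed from it, so series are reproducible independently of the order
#'   in which they are generated.
#' @param phi AR(1) day-to-day autocorrelation of the temperature noise, in
#'   `[0, 1)`.
#' @param sigma stationary standard deviation of the daily noise, degC.
#' @param warming_rates named vector, degC per decade, per scenario; warming
#'   is linear in `year - anchor_year`.
#' @param anchor_year year at which accumulated scenario warming is zero;
#'   defaults to the baseline start so future windows carry the warming
#'   accumulated since the baseline era.
#' @param model_bias additive bias per model, degC (length `n_models`;
#'   defaults to an even spread over about 2 degC).
#' @param model_noise_sd extra independent daily noise added to each model on
#'   top of the shared truth, degC, scaled per model by `noise_inflation`.
#' @param noise_inflation per-model multiplier on `model_noise_sd`.
#' @param obs_noise_sd observation noise of the reference series, degC.
#' @param episode_rate expected heat-dome episodes per warm season (per year).
#' @param episode_min_days,episode_mean_extra episode length is
#'   `episode_min_days + Poisson(episode_mean_extra)` days.
#' @param episode_amp_range uniform range of the episode's additive amplitude,
#'   degC, constant across the episode's days.
#' @param warm_season_doys days of year eligible to start an episode.
#' @param diurnal_offset mean tasmax - tasmin gap, degC.
#' @param tasmin_noise_sd independent noise on tasmin, degC; tasmin is clipped
#'   so tasmax >= tasmin on every day.
#' @param pop_multipliers list per SSP of `c(y2050, y2090)` growth multipliers
#'   applied to the 2020 base population (SSP3 declines by 2090).
#' @param pop_jitter_sd lognormal sdlog of the multiplicative population
#'   jitter; 0 switches jitter off.
#' @return object of class `synthetic_spec`, with a `$cities` table carrying
#'   each city's climatology (`mu`, `amp`, `peak_doy`) and 2020 population.
#' @export
synthetic_spec <- function(n_cities = 10L, n_models = 5L, seed = 1L,
                           phi = 0.7, sigma = 2,
                           warming_rates = c(historical = 0.1, ssp245 = 0.3,
                                             ssp585 = 0.6),
                           anchor_year = 1985L,
                           model_bias = NULL, model_noise_sd = 1,
                           noise_inflation = NULL, obs_noise_sd = 0.3,
                           episode_rate = 1.5, episode_min_days = 3L,
                           episode_mean_extra = 3, episode_amp_range = c(2, 6),
                           warm_season_doys = 135:250,
                           diurnal_offset = 10, tasmin_noise_sd = 0.5,
                           pop_multipliers = list(
                             ssp1 = c(1.15, 1.10), ssp2 = c(1.20, 1.30),
                             ssp3 = c(1.05, 0.88), ssp4 = c(1.12, 1.05),
                             ssp5 = c(1.30, 1.55)),
                           pop_jitter_sd = 0.05) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1): AR(1) non-stationary")
  stopifnot(sigma >= 0, episode_min_days >= 1, n_cities >= 1, n_models >= 1,
            diurnal_offset >= 0)
  if (is.null(model_bias)) {
    model_bias <- if (n_models == 1L) 0 else seq(-1, 1, length.out = n_models)
  }
  if (is.null(noise_inflation)) noise_inflation <- rep(1, n_models)
  stopifnot(length(model_bias) == n_models,
            length(noise_inflation) == n_models)
  spec <- structure(list(
    n_cities = as.integer(n_cities), n_models = as.integer(n_models),
    seed = as.integer(seed), phi = phi, sigma = sigma,
    warming_rates = warming_rates, anchor_year = as.integer(anchor_year),
    model_ids = sprintf("M%02d", seq_len(n_models)),
    model_bias = model_bias, model_noise_sd = model_noise_sd,
    noise_inflation = noise_inflation, obs_noise_sd = obs_noise_sd,
    episode_rate = episode_rate,
    episode_min_days = as.integer(episode_min_days),
    episode_mean_extra = episode_mean_extra,
    episode_amp_range = episode_amp_range,
    warm_season_doys = as.integer(warm_season_doys),
    diurnal_offset = diurnal_offset, tasmin_noise_sd = tasmin_noise_sd,
    pop_multipliers = pop_multipliers, pop_jitter_sd = pop_jitter_sd),
    class = "synthetic_spec")
  spec$cities <- synthetic_cities(spec)
  spec
}

# Deterministic city layout: up to three cities sit ~5 km off one of three
# synthetic coastlines (west meridian, south parallel, east meridian); the
# rest are placed well inland. Climatology and base population are drawn once
# from the spec seed.
synthetic_cities <- function(spec) {
  n <- spec$n_cities
  set.seed(derive_seed(spec$seed, "cities"))
  lon <- lat <- numeric(n)
  coast_group <- rep("Inland", n)
  if (n >= 1) { lon[1] <- -121.95; lat[1] <- 40.0; coast_group[1] <- "WestCoast" }
  if (n >= 2) { lon[2] <- -90.0; lat[2] <- 27.05; coast_group[2] <- "SouthCoast" }
  if (n >= 3) { lon[3] <- -73.95; lat[3] <- 40.5; coast_group[3] <- "EastNorthCoast" }
  if (n >= 4) {
    k <- n - 3L
    lon[4:n] <- -105 + 2.5 * (seq_len(k) - 1) %% 5
    lat[4:n] <- 34 + 2.0 * ((seq_len(k) - 1) %/% 5)
  }
  regions <- c("West", "Southeast", "Northeast",
               rep_len(c("Midwest", "Southwest", "Northeast", "Southeast", "West"),
                       max(0L, n - 3L)))[seq_len(n)]
  data.frame(
    city_id = sprintf("C%02d", seq_len(n)),
    name = sprintf("City %02d", seq_len(n)),
    region = regions, lon = lon, lat = lat, coast_group = coast_group,
    mu = round(runif(n, 12, 28), 2),
    amp = round(runif(n, 8, 14), 2),
    peak_doy = as.integer(round(runif(n, 190, 210))),
    base_pop = round(exp(runif(n, log(3e5), log(8e6)))),
    stringsAsFactors = FALSE)
}

#' Synthetic coastline polylines
#'
#' Three densified polylines: a west-coast meridian, a south-coast parallel,
#' and an east-coast meridian, matching the coastal cities laid out by
#' [synthetic_spec()].
#'
#' @param spec a `synthetic_spec` (unused beyond its presence; the coastline
#'   is fixed geometry).
#' @return list of lon/lat matrices.
#' @export
generate_coastline <- function(spec) {
  list(
    cbind(lon = -122, lat = seq(32, 48, by = 0.25)),
    cbind(lon = seq(-97, -82, by = 0.25), lat = 27),
    cbind(lon = -74, lat = seq(32, 44, by = 0.25)))
}

#' Generate the shared "truth" daily series for one city
#'
#' The truth is `mu + amp * cos(2*pi*(doy - peak)/365) + trend*(year -
#' anchor) + episode(d) + eps(d)`, with `eps` an AR(1) process of coefficient
#' `phi` and stationary standard deviation `sigma`, and episodes additive
#' block shifts confined to the warm season. `tasmin` is `tasmax` minus the
#' diurnal offset plus small independent noise, clipped so tasmax >= tasmin.
#'
#' @param spec a [synthetic_spec()].
#' @param city_id one of `spec$cities$city_id`.
#' @param scenario `"historical"`, `"ssp245"` or `"ssp585"`.
#' @param window a [period_window()].
#' @return list with elements `tasmax` and `tasmin`, each a [daily_series()]
#'   on the noleap calendar; deterministic under the spec seed.
#' @export
generate_truth <- function(spec, city_id, scenario, window) {
  city <- spec$cities[spec$cities$city_id == city_id, ]
  if (nrow(city) != 1L) stop("unknown city_id: ", city_id)
  scenario <- match.arg(scenario, c("historical", "ssp245", "ssp585"))
  rate <- spec$warming_rates[[scenario]] / 10  # degC per year
  cal <- daily_calendar(window$start_year, window$end_year, "noleap")
  n <- nrow(cal)

  set.seed(derive_seed(spec$seed, "truth", city_id, scenario,
                       window$start_year, window$end_year))
  seas <- city$mu + city$amp * cos(2 * pi * (cal$doy - city$peak_doy) / 365)
  warm <- rate * (cal$year - spec$anchor_year)
  # AR(1) noise with stationary sd sigma
  x0 <- rnorm(1, 0, spec$sigma)
  innov <- rnorm(n, 0, spec$sigma * sqrt(1 - spec$phi^2))
  eps <- as.numeric(filter(innov, spec$phi, method = "recursive",
                           init = x0))
  # warm-season heat-dome episodes, additive block shifts
  ep <- numeric(n)
  years <- window$start_year:window$end_year
  for (y in years) {
    n_ep <- rpois(1, spec$episode_rate)
    if (n_ep == 0) next
    for (k in seq_len(n_ep)) {
      start_doy <- sample(spec$warm_season_doys, 1)
      len <- spec$episode_min_days + rpois(1, spec$episode_mean_extra)
      amp <- runif(1, spec$episode_amp_range[1], spec$episode_amp_range[2])
      i0 <- (y - window$start_year) * 365L + start_doy
      idx <- i0:min(i0 + len - 1L, n)
      ep[idx] <- ep[idx] + amp
    }
  }
  tasmax <- seas + warm + ep + eps
  tasmin <- tasmax - spec$diurnal_offset +
    rnorm(n, 0, spec$tasmin_noise_sd)
  tasmin <- pmin(tasmin, tasmax)

  list(
    tasmax = daily_series(city_id, "truth", scenario, "tasmax",
                          cal$year, cal$doy, tasmax),
    tasmin = daily_series(city_id, "truth", scenario, "tasmin",
                          cal$year, cal$doy, tasmin))
}

#' Generate a model ensemble plus reference for one scenario and window
#'
#' Each model is the shared truth plus its additive bias and extra
#' independent noise; the reference is the truth plus small observation
#' noise under `model_id = "reference"`.
#'
#' @inheritParams generate_truth
#' @param cities subset of city ids (default all).
#' @param include_reference include the reference series (typically only
#'   wanted for the baseline window).
#' @return flat list of [daily_series()] (both diurnal variables, all models,
#'   all cities).
#' @export
generate_model_ensemble <- function(spec, scenario, window,
                                    cities = spec$cities$city_id,
                                    include_reference = TRUE) {
  out <- list()
  for (cid in cities) {
    tr <- generate_truth(spec, cid, scenario, window)
    for (v in .DIURNAL_VARS) {
      s <- tr[[v]]
      if (include_reference) {
        set.seed(derive_seed(spec$seed, "obs", cid, scenario, v,
                             window$start_year))
        obs <- s$value_c + rnorm(length(s), 0, spec$obs_noise_sd)
        out[[length(out) + 1L]] <-
          daily_series(cid, .REFERENCE_MODEL, scenario, v, s$year, s$doy, obs)
      }
      for (m in seq_len(spec$n_models)) {
        set.seed(derive_seed(spec$seed, "model", spec$model_ids[m], cid,
                             scenario, v, window$start_year))
        val <- s$value_c + spec$model_bias[m] +
          rnorm(length(s), 0,
                spec$model_noise_sd * spec$noise_inflation[m])
        out[[length(out) + 1L]] <-
          daily_series(cid, spec$model_ids[m], scenario, v, s$year, s$doy, val)
      }
    }
  }
  out
}

#' Generate SSP-style city population trajectories
#'
#' `pop(city, year, ssp) = base(city) * multiplier(ssp, year) * jitter`, with
#' the 2020 value equal to the base in every SSP and multiplicative lognormal
#' jitter (sdlog `spec$pop_jitter_sd`) on the future values.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `city_id, year, ssp, population`, years
#'   2020/2050/2090, SSPs `ssp1..ssp5`; deterministic under the spec seed.
#' @export
generate_population <- function(spec) {
  if (any(spec$cities$base_pop <= 0)) stop("non-positive base population")
  set.seed(derive_seed(spec$seed, "population"))
  ssps <- names(spec$pop_multipliers)
  rows <- list()
  for (ssp in ssps) {
    mult <- spec$pop_multipliers[[ssp]]
    for (i in seq_along(c(2020, 2050, 2090))) {
      yr <- c(2020, 2050, 2090)[i]
      m <- if (yr == 2020) 1 else mult[i - 1L]
      jit <- if (yr == 2020 || spec$pop_jitter_sd == 0) {
        rep(1, spec$n_cities)
      } else {
        rlnorm(spec$n_cities, 0, spec$pop_jitter_sd)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        city_id = spec$cities$city_id, year = yr, ssp = ssp,
        population = spec$cities$base_pop * m * jit,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$city_id, out$ssp, out$year), ]
}
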