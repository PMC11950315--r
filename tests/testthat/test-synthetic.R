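flat_spec <- function(seed = 1, ...) {
  # degenerate climatology: no seasonality, no noise, no episodes, no warming
  sp <- synthetic_spec(n_cities = 3, n_models = 2, seed = seed,
                       sigma = 0, episode_rate = 0, tasmin_noise_sd = 0,
                       warming_rates = c(historical = 0, ssp245 = 0.3,
                                         ssp585 = 0.6), ...)
  sp$cities$amp <- 0
  sp
}

test_that("degenerate spec yields a constant series at the city mean", {
  sp <- flat_spec()
  w <- period_window("baseline", 2000, 2001)
  tr <- generate_truth(sp, "C01", "historical", w)
  mu <- sp$cities$mu[1]
  expect_equal(unique(tr$tasmax$value_c), mu)
  expect_equal(unique(tr$tasmin$value_c), mu - sp$diurnal_offset)
  expect_length(tr$tasmax, 730)
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- synthetic_spec(n_cities = 3, n_models = 2, seed = 99)
  w <- period_window("baseline", 2000, 2004)
  a <- generate_truth(sp, "C02", "ssp245", w)
  b <- generate_truth(sp, "C02", "ssp245", w)
  expect_identical(a$tasmax$value_c, b$tasmax$value_c)
  expect_identical(a$tasmin$value_c, b$tasmin$value_c)
  e1 <- generate_model_ensemble(sp, "historical", w, cities = "C01")
  e2 <- generate_model_ensemble(sp, "historical", w, cities = "C01")
  expect_identical(lapply(e1, `[[`, "value_c"), lapply(e2, `[[`, "value_c"))
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  sp <- flat_spec(seed = 5)
  sp$phi <- 0.7; sp$sigma <- 2
  w <- period_window("baseline", 1985, 2014)  # 30 x 365 days
  tr <- generate_truth(sp, "C01", "historical", w)
  x <- tr$tasmax$value_c
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.7), 0.05)
  # stationary sd close to sigma
  expect_lt(abs(sd(x) - 2), 0.2)
})

test_that("tasmax is never below tasmin and non-stationary phi is rejected", {
  sp <- synthetic_spec(n_cities = 2, n_models = 1, seed = 3)
  w <- period_window("baseline", 2000, 2004)
  for (cid in sp$cities$city_id) {
    tr <- generate_truth(sp, cid, "ssp585", w)
    expect_true(all(tr$tasmax$value_c >= tr$tasmin$value_c))
  }
  expect_error(synthetic_spec(phi = 1), "non-stationary")
  expect_error(synthetic_spec(phi = -0.1), "non-stationary")
})

test_that("scenario warming accumulates between baseline and far future", {
  sp <- synthetic_spec(n_cities = 2, n_models = 1, seed = 8)
  base <- generate_truth(sp, "C01", "ssp585", period_window("b", 1985, 2014))
  far <- generate_truth(sp, "C01", "ssp585", period_window("f", 2065, 2094))
  shift <- mean(far$tasmax$value_c) - mean(base$tasmax$value_c)
  # 0.6 degC/decade, window midpoints 80 years apart -> ~4.8 degC
  expect_lt(abs(shift - 4.8), 1.0)
})

test_that("model ensemble carries biases around the shared truth", {
  sp <- synthetic_spec(n_cities = 1, n_models = 3, seed = 12,
                       model_bias = c(-2, 0, 2), model_noise_sd = 0.1)
  w <- period_window("baseline", 2000, 2009)
  ens <- generate_model_ensemble(sp, "historical", w, include_reference = TRUE)
  expect_length(ens, 8)  # (3 models + reference) x 2 diurnal variables
  tr <- generate_truth(sp, "C01", "historical", w)
  for (s in ens) {
    if (s$diurnal_var != "tasmax") next
    offset <- mean(s$value_c - tr$tasmax$value_c)
    want <- if (s$model_id == "reference") 0 else
      sp$model_bias[match(s$model_id, sp$model_ids)]
    expect_lt(abs(offset - want), 0.1)
  }
})

test_that("population trajectories follow the SSP multipliers", {
  sp <- synthetic_spec(n_cities = 3, n_models = 1, seed = 21,
                       pop_jitter_sd = 0,
                       pop_multipliers = list(ssp1 = c(1.5, 1.0),
                                              ssp3 = c(1.05, 0.88)))
  pop <- generate_population(sp)
  base <- sp$cities$base_pop
  p <- function(ssp, yr) {
    pop$population[pop$ssp == ssp & pop$year == yr][order(
      pop$city_id[pop$ssp == ssp & pop$year == yr])]
  }
  expect_equal(p("ssp1", 2020), base)
  expect_equal(p("ssp1", 2050), base * 1.5)      # multiplier exact, jitter off
  expect_equal(p("ssp1", 2090), base)            # multiplier 1 -> 0% change
  expect_equal(population_change(p("ssp3", 2090), p("ssp3", 2020)),
               rep(-12, 3))                      # SSP3-style decline
  sp$cities$base_pop[1] <- 0
  expect_error(generate_population(sp), "non-positive")
})

test_that("baseline days exceed their own 95th-percentile threshold ~5% of the time", {
  sp <- synthetic_spec(n_cities = 1, n_models = 1, seed = 31)
  w <- period_window("baseline", 1985, 2014)
  tr <- generate_truth(sp, "C01", "historical", w)
  thr <- baseline_threshold(tr$tasmax, w, q = 0.95)
  frac <- mean(tr$tasmax$value_c > thr$value)
  expect_gt(length(tr$tasmax), 10000)
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("a single-model ensemble scores exactly n_cities points", {
  sp <- synthetic_spec(n_cities = 3, n_models = 1, seed = 17)
  w <- period_window("baseline", 1995, 2004)
  ens <- generate_model_ensemble(sp, "historical", w)
  idx <- compute_annual_indices(ens, ens, w)
  pm <- period_mean_indices(idx, w)
  rk <- rank_models(pm[pm$model_id != "reference", ],
                    pm[pm$model_id == "reference", ])
  expect_equal(rk$scores$cumulative_score, 3)  # n_cities x 1
})
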