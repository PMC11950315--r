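# Heat-risk overlay: normalized population quantities multiplied with the
# final CHI. Two variants: absolute risk (CHI x normalized population) and
# change-based risk (CHI x normalized population change vs 2020). Population
# normalization is computed within one (SSP, horizon) slice.

#' Population change relative to 2020
#'
#' @param pop_future,pop_2020 persons; `pop_2020` must be positive.
#' @return percentage change; negative values permitted (declining SSPs).
#' @export
population_change <- function(pop_future, pop_2020) {
  if (any(pop_2020 <= 0)) stop("2020 population must be positive")
  (pop_future - pop_2020) / pop_2020 * 100
}

#' Min-max normalize a population quantity across cities
#'
#' Applies to absolute populations or to signed percentage changes (the
#' most-declining city maps to 0). Degenerate all-equal input maps to 0 with
#' the `degenerate` attribute set.
#'
#' @param values named numeric (city -> quantity), length >= 2.
#' @return values scaled to `[0, 1]`.
#' @export
normalize_population <- function(values) {
  minmax_normalize(values)
}

#' The two heat-risk products
#'
#' @param chi_final,pop_norm,pop_change_norm per-city values in `[0, 1]`.
#' @return data.frame `risk_abs = chi_final * pop_norm`,
#'   `risk_change = chi_final * pop_change_norm`.
#' @export
risk_products <- function(chi_final, pop_norm, pop_change_norm) {
  stopifnot(all(chi_final >= 0 & chi_final <= 1, na.rm = TRUE),
            all(pop_norm >= 0 & pop_norm <= 1, na.rm = TRUE),
            all(pop_change_norm >= 0 & pop_change_norm <= 1, na.rm = TRUE))
  data.frame(risk_abs = chi_final * pop_norm,
             risk_change = chi_final * pop_change_norm)
}

#' Build the risk table for one (climate scenario, SSP, horizon) slice
#'
#' Joins the ensemble CHI of the matching period with the population
#' trajectory of one SSP at one horizon year, normalizes population and
#' population change across cities within the slice, and multiplies.
#'
#' @param chi_table output of [compute_chi()]; the `model_id = "ensemble"`
#'   rows of one scenario/period are used.
#' @param population table from [generate_population()] (or same columns).
#' @param ssp e.g. `"ssp2"`.
#' @param horizon 2050 or 2090.
#' @return data.frame of RiskRecords: `city_id, scenario, ssp, horizon, pop,
#'   pop_change_pct, pop_norm, pop_change_norm, chi_final, risk_abs,
#'   risk_change`.
#' @export
risk_table <- function(chi_table, population, ssp, horizon) {
  stopifnot(horizon %in% c(2050, 2090))
  chi <- chi_table[chi_table$model_id == "ensemble", ]
  if (nrow(chi) == 0L) stop("chi_table has no ensemble rows")
  pop_f <- population[population$ssp == ssp & population$year == horizon, ]
  pop_0 <- population[population$ssp == ssp & population$year == 2020, ]
  cities <- chi$city_id
  pf <- pop_f$population[match(cities, pop_f$city_id)]
  p0 <- pop_0$population[match(cities, pop_0$city_id)]
  if (anyNA(pf) || anyNA(p0)) stop("population table does not cover all cities")
  chg <- population_change(pf, p0)
  data.frame(city_id = cities, scenario = chi$scenario, ssp = ssp,
             horizon = horizon, pop = pf, pop_change_pct = chg,
             pop_norm = as.numeric(normalize_population(pf)),
             pop_change_norm = as.numeric(normalize_population(chg)),
             chi_final = chi$chi_final,
             risk_abs = chi$chi_final * as.numeric(normalize_population(pf)),
             risk_change = chi$chi_final * as.numeric(normalize_population(chg)),
             stringsAsFactors = FALSE)
}

#' Ranked hotspot table by region
#'
#' Orders cities by risk descending within each region, attaches the
#' slice-wide rank, ties broken by `city_id` ascending. All records must
#' share one (scenario, SSP, horizon) slice.
#'
#' @param risk data.frame from [risk_table()].
#' @param region_map data.frame `city_id, region`.
#' @param mode `"abs"` or `"change"` - which risk product to rank on.
#' @return the risk records with `region` and `rank` columns, sorted by
#'   region then risk descending.
#' @export
hotspot_table <- function(risk, region_map, mode = c("abs", "change")) {
  mode <- match.arg(mode)
  slice <- unique(risk[, c("scenario", "ssp", "horizon")])
  if (nrow(slice) != 1L) stop("records span more than one (scenario, ssp, horizon) slice")
  col <- if (mode == "abs") "risk_abs" else "risk_change"
  risk$region <- region_map$region[match(risk$city_id, region_map$city_id)]
  if (anyNA(risk$region)) stop("city without region: ",
                               risk$city_id[is.na(risk$region)][1])
  o <- order(-risk[[col]], risk$city_id)
  risk$rank <- NA_integer_
  risk$rank[o] <- seq_len(nrow(risk))
  risk[order(risk$region, -risk[[col]], risk$city_id), ]
}
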