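# Model evaluation against the reference dataset: absolute deviations of the
# period-mean indices, per-city comprehensive ranks, a rank-points scheme
# (rank 1 of n earns n points, rank n earns 1), cumulative scores across
# cities, and selection of the models that strictly surpass the
# half-maximum score threshold.

#' Absolute deviations of model period means from the reference
#'
#' @param model_means,reference_means data.frames from
#'   [period_mean_indices()] (columns `city_id, model_id, diurnal_var,
#'   index, mean`); `reference_means` must hold a single `model_id`. When
#'   both diurnal variables are supplied the deviation table keeps them
#'   distinct, so ranking averages over all ten index-variable combinations.
#' @return data.frame `model_id, city_id, diurnal_var, index, deviation`;
#'   a deviation is `NA` only where an intensity mean is missing on either
#'   side.
#' @export
index_deviations <- function(model_means, reference_means) {
  if (length(unique(reference_means$model_id)) != 1L) {
    stop("reference_means must contain exactly one model_id")
  }
  key <- function(d) paste(d$city_id, d$diurnal_var, d$index, sep = "|")
  ref <- reference_means
  miss <- setdiff(unique(key(model_means)), key(ref))
  if (length(miss)) {
    stop("reference lacks entries for: ", paste(head(miss, 5), collapse = "; "))
  }
  ref_val <- setNames(ref$mean, key(ref))
  data.frame(model_id = model_means$model_id, city_id = model_means$city_id,
             diurnal_var = model_means$diurnal_var, index = model_means$index,
             deviation = abs(model_means$mean - unname(ref_val[key(model_means)])),
             stringsAsFactors = FALSE)
}

#' Comprehensive per-city model ranking
#'
#' Within one city, models are ranked per index by deviation (rank 1 =
#' smallest, ties share the average of the tied positions); the per-index
#' ranks are averaged per model (an index whose deviation is missing for a
#' model is dropped from that model's average, with the divisor reduced);
#' the averaged ranks are then converted to an ordinal 1..n ordering, ties
#' broken by `model_id` ascending.
#'
#' @param dev deviation table from [index_deviations()].
#' @param city a `city_id` present in `dev`.
#' @return data.frame `model_id, avg_rank, rank, n_indices` for that city.
#' @export
comprehensive_rank <- function(dev, city) {
  d <- dev[dev$city_id == city, ]
  if (nrow(d) == 0L) stop("city not present in deviation table: ", city)
  models <- sort(unique(d$model_id))
  # a single-model ensemble is degenerate but well defined: it ranks first
  if (all(is.na(d$deviation))) stop("all deviations missing for city ", city)
  d$slot <- paste(d$diurnal_var, d$index, sep = "|")
  per_index <- split(d, d$slot)
  rank_rows <- lapply(per_index, function(g) {
    ok <- !is.na(g$deviation)
    r <- rep(NA_real_, nrow(g))
    r[ok] <- rank(g$deviation[ok], ties.method = "average")
    data.frame(model_id = g$model_id, r = r, stringsAsFactors = FALSE)
  })
  rr <- do.call(rbind, rank_rows)
  avg <- vapply(models, function(m) {
    v <- rr$r[rr$model_id == m]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  n_ix <- vapply(models, function(m) sum(!is.na(rr$r[rr$model_id == m])),
                 integer(1))
  ord <- order(avg, models)
  out <- data.frame(model_id = models, avg_rank = unname(avg),
                    rank = NA_integer_, n_indices = unname(n_ix),
                    stringsAsFactors = FALSE)
  out$rank[ord] <- seq_along(models)
  out[order(out$rank), ]
}

#' Points awarded for a per-city rank
#'
#' Rank 1 of `n_models` earns `n_models` points, descending linearly to 1
#' point for the last rank (with 29 models: 29 points for first, 1 for
#' last).
#'
#' @param rank integer rank(s), 1-based.
#' @param n_models ensemble size.
#' @return numeric points, `n_models - rank + 1`.
#' @export
award_points <- function(rank, n_models) {
  if (any(rank < 1 | rank > n_models)) {
    stop("rank out of range 1..", n_models)
  }
  n_models - rank + 1
}

#' Cumulative scores and half-maximum selection
#'
#' Sums each model's per-city points, computes the selection threshold as
#' `selection_fraction * n_cities * n_models` (half the maximum achievable
#' score under the default 0.5 — with 50 cities and 29 models, 725 of 1450),
#' and flags models whose score strictly surpasses it.
#'
#' @param per_city_points data.frame `model_id, city_id, points` with every
#'   model scored in every city.
#' @param n_cities,n_models ensemble dimensions.
#' @param selection_fraction fraction of the maximum score; default 0.5.
#' @return data.frame `model_id, cumulative_score, threshold, selected`,
#'   sorted by score descending (ties by `model_id`).
#' @export
cumulative_and_select <- function(per_city_points, n_cities, n_models,
                                  selection_fraction = 0.5) {
  counts <- table(per_city_points$model_id)
  if (any(counts != n_cities)) {
    stop("model ", names(counts)[counts != n_cities][1],
         " is not scored in every city")
  }
  score <- tapply(per_city_points$points, per_city_points$model_id, sum)
  threshold <- selection_fraction * n_cities * n_models
  out <- data.frame(model_id = names(score),
                    cumulative_score = as.numeric(score),
                    threshold = threshold,
                    selected = as.numeric(score) > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cumulative_score, out$model_id), ]
  rownames(out) <- NULL
  out
}

#' Full model evaluation: deviations, ranks, points, selection
#'
#' @inheritParams index_deviations
#' @param selection_fraction see [cumulative_and_select()].
#' @return list with `deviations`, `ranks` (per city), and `scores` (the
#'   ModelScore table).
#' @export
rank_models <- function(model_means, reference_means,
                        selection_fraction = 0.5) {
  dev <- index_deviations(model_means, reference_means)
  cities <- sort(unique(dev$city_id))
  models <- sort(unique(dev$model_id))
  n_models <- length(models)
  ranks <- lapply(cities, function(ct) {
    r <- comprehensive_rank(dev, ct)
    r$city_id <- ct
    r$points <- award_points(r$rank, n_models)
    r
  })
  ranks <- do.call(rbind, ranks)
  scores <- cumulative_and_select(
    ranks[, c("model_id", "city_id", "points")],
    n_cities = length(cities), n_models = n_models,
    selection_fraction = selection_fraction)
  list(deviations = dev, ranks = ranks, scores = scores)
}

#' Squared Pearson correlation of two daily series
#'
#' Used to validate the reference dataset against station observations.
#' Missing values are removed pairwise; at least 3 complete pairs are
#' required. Zero variance in either series leaves the result undefined
#' (`NA`, with a warning), never 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return squared Pearson correlation in `[0, 1]`, or `NA` if undefined.
#' @export
r_squared <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- complete.cases(a, b)
  if (sum(ok) < 3L) stop("need at least 3 overlapping non-missing pairs")
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance: r-squared undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}
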