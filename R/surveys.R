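# Synthetic household travel surveys: weighted person and trip records
# drawn from the ground truth with a binomial sampling design, so
# Horvitz-Thompson expansion is unbiased with known design variance.

#' Generate weighted travel-survey tables
#'
#' For each survey year, draws person records per zone/sex/age cell by
#' binomial sampling of the true bicyclist population (inclusion
#' probability `sampling_fraction`, design weight its inverse) plus a
#' background of non-bicyclist persons, and trip records by binomial
#' sampling of the true origin-destination flows. Weighted (expanded)
#' totals are therefore unbiased for the ground truth with standard error
#' `sqrt(N (1 - f) / f)`.
#'
#' @param zones a `zone_map`.
#' @param years survey years (strictly increasing; default the five
#'   irregular survey waves 2005, 2011, 2014, 2015, 2017).
#' @param trend bicyclist growth spec ([default_trend()]).
#' @param seed integer seed.
#' @param truth optional `ground_truth`; built from `zones` when missing.
#' @param sampling_fraction person inclusion probability.
#' @param trip_fraction trip inclusion probability.
#' @return list of survey data frames (one per year; columns `year`, `kind`,
#'   `weight`, `sex`, `age_group`, `home_zone`, `origin_zone`, `dest_zone`,
#'   `is_bicyclist`), with the `ground_truth` attached as attribute "truth".
#' @export
generate_surveys <- function(zones, years = c(2005, 2011, 2014, 2015, 2017),
                             trend = default_trend(), seed = 1L,
                             truth = NULL, sampling_fraction = 0.05,
                             trip_fraction = 0.02) {
  if (length(years) == 0) stop("years must be non-empty")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (is.null(truth))
    truth <- make_ground_truth(list(zones = zones, network = NULL),
                               survey_years = years, trend = trend, seed = seed)
  f <- sampling_fraction
  ft <- trip_fraction
  out <- with_seed(child_seed(seed, 2), lapply(years, function(y) {
    pop <- truth$true_population[truth$true_population$year == y, ]
    n_cell <- stats::rbinom(nrow(pop), round(pop$population), f)
    idx <- rep(seq_len(nrow(pop)), n_cell)
    persons <- data.frame(
      year = y, kind = "person", weight = 1 / f,
      sex = pop$sex[idx], age_group = pop$age_group[idx],
      home_zone = pop$zone_id[idx],
      origin_zone = NA_character_, dest_zone = NA_character_,
      is_bicyclist = TRUE, stringsAsFactors = FALSE)

    # non-bicyclist background (20x the bicyclist population, thinner sample)
    fn <- f / 20
    nb_cell <- stats::rbinom(nrow(pop), round(20 * pop$population), fn)
    idx2 <- rep(seq_len(nrow(pop)), nb_cell)
    nonbic <- data.frame(
      year = y, kind = "person", weight = 1 / fn,
      sex = pop$sex[idx2], age_group = pop$age_group[idx2],
      home_zone = pop$zone_id[idx2],
      origin_zone = NA_character_, dest_zone = NA_character_,
      is_bicyclist = FALSE, stringsAsFactors = FALSE)

    total_trips <- trend_total(truth$trend, y) * truth$trips_per_bicyclist
    fl <- truth$od_flows
    tr_cell <- stats::rbinom(nrow(fl), round(fl$share * total_trips), ft)
    idx3 <- rep(seq_len(nrow(fl)), tr_cell)
    cv <- if (length(idx3)) sample_covariates(length(idx3)) else NULL
    trips <- data.frame(
      year = y, kind = "trip", weight = 1 / ft,
      sex = if (length(idx3)) cv$sex else character(0),
      age_group = if (length(idx3)) as.character(age_to_group(cv$age)) else character(0),
      home_zone = fl$origin_zone[idx3],
      origin_zone = fl$origin_zone[idx3], dest_zone = fl$dest_zone[idx3],
      is_bicyclist = TRUE, stringsAsFactors = FALSE)

    rbind(persons, nonbic, trips)
  }))
  names(out) <- as.character(years)
  attr(out, "truth") <- truth
  out
}
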