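# Ground truth for the synthetic city: true bicyclist population, true
# origin-destination flows and daily kilometers traveled, and the true
# fatality-risk model. Everything downstream is validated against this.

#' Default bicyclist growth trend
#'
#' The default scenario grows the commuter-bicyclist population three-fold
#' between 2011 and 2017 (annual factor `3^(1/6)`), starting from 10,000
#' bicyclists in 2011.
#'
#' @param base_total bicyclists in `base_year`.
#' @param base_year reference year.
#' @param annual_factor multiplicative yearly growth.
#' @return a trend spec list.
#' @export
default_trend <- function(base_total = 10000, base_year = 2011,
                          annual_factor = 3^(1/6)) {
  list(kind = "exponential", base_total = base_total, base_year = base_year,
       annual_factor = annual_factor)
}

#' Constant-population trend
#' @param total bicyclists in every year.
#' @return a trend spec list.
#' @export
constant_trend <- function(total = 10000) {
  list(kind = "constant", total = total)
}

#' Total bicyclists implied by a trend spec
#' @param trend a trend spec from [default_trend()] or [constant_trend()].
#' @param year numeric vector of years.
#' @return numeric vector of totals.
#' @export
trend_total <- function(trend, year) {
  switch(trend$kind,
    constant = rep(trend$total, length(year)),
    exponential = trend$base_total * trend$annual_factor^(year - trend$base_year),
    stop("unknown trend kind: ", trend$kind))
}

# Covariate distributions shared by the collision generator and by the
# intercept-centering step of default_risk(). `field` controls whether the
# terrain-slope covariate is drawn from the spatial field (needs x, y) or
# its marginal stand-in.
vehicle_type_levels <- function() {
  c("automobile", "transmilenio", "cargo", "bus", "motorcycle", "other")
}

vehicle_type_probs <- function() {
  c(automobile = 0.45, transmilenio = 0.03, cargo = 0.08, bus = 0.12,
    motorcycle = 0.25, other = 0.07)
}

# Smooth spatial terrain-slope field over the window (percent grade).
slope_field <- function(x, y, window) {
  w <- window[3] - window[1]; h <- window[4] - window[2]
  3 + 2.6 * sin(2 * pi * (x - window[1]) / w) *
    sin(2 * pi * (y - window[2]) / h)
}

sample_covariates <- function(n, window = NULL, x = NULL, y = NULL) {
  vt <- sample(vehicle_type_levels(), n, replace = TRUE,
               prob = vehicle_type_probs())
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25))
  age <- pmin(85, 15 + stats::rgamma(n, shape = 3, scale = 7))
  night <- stats::runif(n) < 0.18
  tod <- ifelse(night, stats::rnorm(n, 1, 2), stats::rnorm(n, 14, 3.5)) %% 24
  slope <- if (is.null(x)) {
    pmax(0, 3 + 2.6 * sin(stats::runif(n, 0, 2 * pi)) *
           sin(stats::runif(n, 0, 2 * pi)))
  } else {
    pmax(0, slope_field(x, y, window) + stats::rnorm(n, 0, 0.3))
  }
  data.frame(vehicle_type = vt, sex = sex, age = age, time_of_day = tod,
             slope_pct = slope, stringsAsFactors = FALSE)
}

#' Default fatality-risk specification
#'
#' Linear log-odds effects for vehicle type (magnitudes echoing heavy-vs-light
#' vehicle contrasts: cargo +2.0, motorcycle -0.8 against an automobile
#' baseline) and infrastructure flags, plus smooth effects: a hinge in
#' terrain slope rising after 3% grade, a night-peaked circadian curve in
#' time of day, and a hinge in age rising after 40. The intercept is centered
#' (by a fixed internal Monte-Carlo draw) so the marginal fatality fraction
#' equals `marginal` under the generator's covariate distributions.
#'
#' @param marginal target marginal fatality fraction (default 0.036, the
#'   class imbalance typical of urban bicyclist collision registries).
#' @return a risk spec list (`intercept`, `linear`, `smooth`).
#' @export
default_risk <- function(marginal = 0.036) {
  linear <- list(
    vehicle_type = c(automobile = 0, transmilenio = 1.2, cargo = 2.0,
                     bus = 1.0, motorcycle = -0.8, other = 0.6),
    sex = c(F = 0, M = 0.1),
    on_bike_path = -0.5,
    lts4 = -0.3,
    transit_presence = 0.3)
  smooth <- list(
    slope_pct = function(s) 0.35 * pmax(s - 3, 0),
    time_of_day = function(t) 0.5 * cos(2 * pi * (t - 1) / 24),
    age = function(a) 0.025 * pmax(a - 40, 0))
  risk <- list(intercept = 0, linear = linear, smooth = smooth,
               marginal = marginal)
  risk$intercept <- center_intercept(risk, marginal)
  risk
}

#' Null fatality-risk specification
#'
#' All linear and smooth effects zero; the intercept is the logit of the
#' marginal fatality fraction, so generated fatality indicators are i.i.d.
#' Bernoulli(`marginal`).
#'
#' @inheritParams default_risk
#' @return a risk spec list.
#' @export
null_risk <- function(marginal = 0.036) {
  list(intercept = stats::qlogis(marginal),
       linear = list(
         vehicle_type = c(automobile = 0, transmilenio = 0, cargo = 0,
                          bus = 0, motorcycle = 0, other = 0),
         sex = c(F = 0, M = 0), on_bike_path = 0, lts4 = 0,
         transit_presence = 0),
       smooth = list(), marginal = marginal)
}

# Choose the intercept so E[plogis(intercept + eta)] = marginal, using a
# fixed internal covariate draw (deterministic, independent of user seeds).
center_intercept <- function(risk, marginal) {
  eta <- with_seed(20260920, {
    cv <- sample_covariates(20000)
    cv$on_bike_path <- stats::rbinom(20000, 1, 0.12)
    cv$lts4 <- stats::rbinom(20000, 1, 0.25)
    cv$transit_presence <- stats::rbinom(20000, 1, 0.30)
    risk_eta(cv, risk, intercept = 0)
  })
  stats::uniroot(function(b) mean(stats::plogis(b + eta)) - marginal,
                 interval = c(-15, 5), tol = 1e-10)$root
}

# Linear + smooth contribution to the fatality log-odds (without hotspot
# boosts). `intercept` overrides risk$intercept when given.
risk_eta <- function(covs, risk, intercept = NULL) {
  eta <- rep(intercept %||% risk$intercept, nrow(covs))
  lin <- risk$linear
  if (!is.null(lin$vehicle_type)) eta <- eta + lin$vehicle_type[covs$vehicle_type]
  if (!is.null(lin$sex)) eta <- eta + lin$sex[covs$sex]
  for (nm in c("on_bike_path", "lts4", "transit_presence")) {
    if (!is.null(lin[[nm]]) && nm %in% names(covs))
      eta <- eta + lin[[nm]] * covs[[nm]]
  }
  if (!is.null(lin$weekday) && "weekday" %in% names(covs))
    eta <- eta + lin$weekday[covs$weekday]
  for (nm in names(risk$smooth)) {
    if (nm %in% names(covs)) eta <- eta + risk$smooth[[nm]](covs[[nm]])
  }
  unname(eta)
}

#' Build the ground truth for a synthetic city
#'
#' Lays down the true bicyclist population per zone, year, and sex-by-age
#' stratum; true origin-destination trip flows with a gravity-type distance
#' decay; true per-zone daily kilometers traveled (routing each flow over
#' the network and splitting the path across zone polygons); planted fatal
#' hotspot centers; and the true fatality-risk model.
#'
#' @param city list with `zones` and `network` from [generate_city()]
#'   (`network` may be NULL, in which case per-zone kilometers are skipped).
#' @param survey_years years with a travel survey.
#' @param period analysis years for collisions.
#' @param trend bicyclist growth spec ([default_trend()]).
#' @param risk fatality-risk spec ([default_risk()]).
#' @param trips_per_bicyclist daily utilitarian trips per bicyclist.
#' @param n_od number of origin-destination flows (default `15 * n_zones`).
#' @param n_hotspots planted fatal hotspot centers.
#' @param hotspot_radius radius (m) of each planted center.
#' @param hotspot_multiplier odds multiplier for fatality inside a center.
#' @param seed integer seed.
#' @return a `ground_truth` list: `true_population`, `od_flows`,
#'   `true_vkmt`, `linear_log_odds`, `smooth_log_odds`, `hotspot_centers`,
#'   `risk`, `zone_weight`, `trend`, `years`, `period`, `seed`.
#' @export
make_ground_truth <- function(city,
                              survey_years = c(2005, 2011, 2014, 2015, 2017),
                              period = 2011:2017,
                              trend = default_trend(),
                              risk = default_risk(),
                              trips_per_bicyclist = 2,
                              n_od = NULL,
                              n_hotspots = 3,
                              hotspot_radius = 1200,
                              hotspot_multiplier = 10,
                              seed = 1L) {
  zones <- city$zones
  zone_ids <- vapply(zones$zones, `[[`, character(1), "zone_id")
  nz <- length(zone_ids)
  years <- sort(unique(c(survey_years, period)))
  n_od <- n_od %||% (15L * nz)

  with_seed(child_seed(seed, 1), {
    areas <- vapply(zones$zones, function(z) polygon_area(z$polygon), 1)
    zw <- areas * exp(stats::rnorm(nz, 0, 0.20))
    zw <- zw / sum(zw)

    ages <- age_group_levels()
    age_p <- stats::dgamma(seq(7, 87, by = 5) - 5, shape = 3, scale = 11)
    age_p <- age_p / sum(age_p)
    sex_p <- c(M = 0.75, F = 0.25)

    cells <- expand.grid(zone_id = zone_ids, sex = c("M", "F"),
                         age_group = ages, stringsAsFactors = FALSE)
    frac <- zw[match(cells$zone_id, zone_ids)] *
      sex_p[cells$sex] * age_p[match(cells$age_group, ages)]
    true_population <- do.call(rbind, lapply(years, function(y) {
      data.frame(zone_id = cells$zone_id, year = y, sex = cells$sex,
                 age_group = cells$age_group,
                 population = trend_total(trend, y) * frac,
                 stringsAsFactors = FALSE)
    }))
    rownames(true_population) <- NULL

    # gravity-type OD flows between zone centroids
    cents <- zone_centroids(zones)
    o <- sample(nz, n_od, replace = TRUE, prob = zw)
    dmat <- as.matrix(stats::dist(cents[, c("x", "y")]))
    d <- vapply(o, function(oi) {
      p <- zw * exp(-dmat[oi, ] / 5000)
      sample(nz, 1, prob = p)
    }, integer(1))
    gshare <- stats::rgamma(n_od, shape = 2, rate = 1)
    gshare <- gshare / sum(gshare)
    od_flows <- data.frame(origin_zone = zone_ids[o], dest_zone = zone_ids[d],
                           share = gshare, stringsAsFactors = FALSE)

    true_vkmt <- NULL
    if (!is.null(city$network)) {
      alloc <- allocate_od_flows(city$network, zones, od_flows)
      od_flows$path_km <- alloc$path_km
      base_trips <- trend_total(trend, years) * trips_per_bicyclist
      # per-zone daily km for each year: flow shares scale with total trips
      true_vkmt <- do.call(rbind, lapply(seq_along(years), function(i) {
        km <- alloc$zone_km
        data.frame(zone_id = km$zone_id, year = years[i],
                   daily_vkmt = km$km_per_trip_total * base_trips[i],
                   stringsAsFactors = FALSE)
      }))
      # zones no flow crosses still get a row
      missing <- setdiff(zone_ids, unique(true_vkmt$zone_id))
      if (length(missing)) {
        extra <- expand.grid(zone_id = missing, year = years,
                             stringsAsFactors = FALSE)
        extra$daily_vkmt <- 0
        true_vkmt <- rbind(true_vkmt, extra)
      }
      rownames(true_vkmt) <- NULL
    }

    # hotspot centers live where cycling volume is substantial: sample
    # among the top quartile of zones by exposure density (kilometers
    # traveled per unit area; residence weight density as fallback), so a
    # planted cluster generates enough fatal events to constitute a
    # hotspot in the observable sense. A margin from the window edge is
    # enforced by rejection within the zone.
    win <- zones$window
    mx <- 0.1 * (win[3] - win[1]); my <- 0.1 * (win[4] - win[2])
    dens <- if (!is.null(true_vkmt)) {
      vy <- true_vkmt[true_vkmt$year == max(years), ]
      v <- vy$daily_vkmt[match(zone_ids, vy$zone_id)]
      v[is.na(v)] <- 0
      if (sum(v) > 0) v / areas else zw / areas
    } else zw / areas
    top <- which(dens >= stats::quantile(dens, 0.75))
    hz <- top[sample.int(length(top), n_hotspots, replace = TRUE,
                         prob = dens[top])]
    hpts <- t(vapply(hz, function(z) {
      for (try in 1:50) {
        p <- runif_in_polygon(1, zones$zones[[z]]$polygon)
        if (p[1] >= win[1] + mx && p[1] <= win[3] - mx &&
            p[2] >= win[2] + my && p[2] <= win[4] - my) return(c(p[1], p[2]))
      }
      c(min(max(p[1], win[1] + mx), win[3] - mx),
        min(max(p[2], win[2] + my), win[4] - my))
    }, numeric(2)))
    hotspot_centers <- data.frame(
      x = hpts[, 1], y = hpts[, 2],
      radius = hotspot_radius,
      multiplier = hotspot_multiplier)

    structure(list(
      true_population = true_population,
      od_flows = od_flows,
      true_vkmt = true_vkmt,
      linear_log_odds = risk$linear,
      smooth_log_odds = risk$smooth,
      hotspot_centers = hotspot_centers,
      risk = risk,
      zone_weight = stats::setNames(zw, zone_ids),
      trips_per_bicyclist = trips_per_bicyclist,
      trend = trend, years = years, period = period, seed = seed),
      class = "ground_truth")
  })
}

# Route every OD flow and split its path across zones. Returns per-flow path
# lengths (km) and, per zone, the flow-share-weighted km per total daily trip.
allocate_od_flows <- function(network, zones, od_flows) {
  cents <- zone_centroids(zones)
  snap <- nearest_node(network, cents$x, cents$y)
  names(snap) <- cents$zone_id
  g <- network_graph(network)
  keys <- paste(od_flows$origin_zone, od_flows$dest_zone)
  uniq <- !duplicated(keys)
  zone_acc <- new.env(parent = emptyenv())
  path_km_u <- numeric(sum(uniq))
  seg_list <- vector("list", sum(uniq))
  uidx <- which(uniq)
  for (k in seq_along(uidx)) {
    i <- uidx[k]
    p <- shortest_path(network, zones, od_flows$origin_zone[i],
                       od_flows$dest_zone[i], graph = g, snap = snap)
    path_km_u[k] <- p$length_km
    if (p$length_km > 0) {
      coords <- p$coords
      seg_list[[k]] <- split_path_by_zones(coords, zones)
    }
  }
  ukeys <- keys[uniq]
  path_km <- path_km_u[match(keys, ukeys)]
  # weight per zone: sum over flows of share * in-zone km; scaled later by
  # total daily trips
  acc <- list()
  for (i in seq_along(keys)) {
    k <- match(keys[i], ukeys)
    segs <- seg_list[[k]]
    if (is.null(segs) || nrow(segs) == 0) next
    w <- od_flows$share[i] * segs$length / 1000
    for (j in seq_len(nrow(segs))) {
      zid <- segs$zone_id[j]
      acc[[zid]] <- (acc[[zid]] %||% 0) + w[j]
    }
  }
  zone_km <- data.frame(zone_id = names(acc),
                        km_per_trip_total = as.numeric(unlist(acc)),
                        stringsAsFactors = FALSE)
  list(path_km = path_km, zone_km = zone_km)
}
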