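# Synthetic collision events: a marked point process over the city whose
# spatial intensity follows zone exposure, with fatality drawn from the
# true binomial risk model and boosted inside planted hotspot centers.

#' Generate a synthetic collision table
#'
#' Places collision events over the study window with spatial intensity
#' proportional to each zone's true daily kilometers traveled (uniform
#' within zone), or optionally along sampled origin-destination shortest
#' paths. Each event gets individual and contextual covariates (vehicle
#' type, sex, age, weekday, time of day, terrain slope from a smooth
#' spatial field, road-segment attributes and their traffic-stress rating),
#' and a fatality indicator drawn from the binomial log-odds model in
#' `risk`, with log-odds boosted by `log(multiplier)` inside each planted
#' hotspot center.
#'
#' @param zones a `zone_map`.
#' @param network a `road_network`.
#' @param truth a `ground_truth` with `true_vkmt` (total exposure must be
#'   positive).
#' @param period analysis years (default the truth's period).
#' @param seed integer seed.
#' @param n_events total events over the period (default 9950, the size of
#'   a seven-year city registry with a ~3.6% fatal fraction).
#' @param risk fatality-risk spec; defaults to the truth's.
#' @param placement "zone_vkmt" (default) or "od_path".
#' @param growth total multiplicative growth of yearly event counts across
#'   the period (default 1.4).
#' @return data.frame, one row per bicyclist per collision: event_id, x, y,
#'   zone_id, datetime, year, month, fatal, sex, age, age_group,
#'   vehicle_type, weekday, time_of_day, slope_pct, surface_failures,
#'   lighting_pct, on_bike_path, transit_presence, n_lanes, lane_width,
#'   speed_limit, lts, lts4.
#' @export
generate_collisions <- function(zones, network, truth,
                                period = NULL, seed = 1L,
                                n_events = 9950, risk = NULL,
                                placement = c("zone_vkmt", "od_path"),
                                growth = 1.4) {
  placement <- match.arg(placement)
  period <- period %||% truth$period
  risk <- risk %||% truth$risk
  if (is.null(truth$true_vkmt) || sum(truth$true_vkmt$daily_vkmt) <= 0)
    stop("zero total exposure: ground truth has no positive daily_vkmt")
  pf <- stats::plogis(risk$intercept)
  if (pf <= 0 || pf >= 0.2)
    stop("risk intercept must imply a marginal fatality fraction in (0, 0.2)")

  with_seed(child_seed(seed, 3), {
    span <- max(period) - min(period)
    wy <- if (span == 0) 1 else growth^((period - min(period)) / span)
    ny <- as.vector(stats::rmultinom(1, n_events, wy))
    zone_ids <- vapply(zones$zones, `[[`, character(1), "zone_id")

    rows <- vector("list", length(period))
    for (k in seq_along(period)) {
      y <- period[k]; n <- ny[k]
      if (n == 0) next
      if (placement == "zone_vkmt") {
        vk <- truth$true_vkmt[truth$true_vkmt$year == y, ]
        pz <- vk$daily_vkmt[match(zone_ids, vk$zone_id)]
        pz[is.na(pz)] <- 0
        zi <- sample(seq_along(zone_ids), n, replace = TRUE, prob = pz)
        pts <- matrix(0, n, 2)
        for (z in sort(unique(zi))) {
          sel <- zi == z
          pts[sel, ] <- runif_in_polygon(sum(sel), zones$zones[[z]]$polygon)
        }
        zone_id <- zone_ids[zi]
      } else {
        pts <- matrix(0, n, 2)
        fl <- truth$od_flows
        g <- network_graph(network)
        cents <- zone_centroids(zones)
        snap <- stats::setNames(nearest_node(network, cents$x, cents$y),
                                cents$zone_id)
        fi <- sample(nrow(fl), n, replace = TRUE, prob = fl$share)
        for (i in seq_len(n)) {
          p <- shortest_path(network, zones, fl$origin_zone[fi[i]],
                             fl$dest_zone[fi[i]], graph = g, snap = snap)
          pts[i, ] <- point_along_path(p$coords, stats::runif(1))
        }
        zone_id <- locate_zone(pts[, 1], pts[, 2], zones, tol = 1e-6)
      }

      cv <- sample_covariates(n, window = zones$window,
                              x = pts[, 1], y = pts[, 2])
      ei <- sample(nrow(network$edges), n, replace = TRUE)
      ed <- network$edges[ei, ]
      lts <- lts_rating(data.frame(
        lanes = ed$lanes, lane_width = ed$lane_width,
        speed_limit = ed$speed_limit, has_bike_path = ed$has_bike_path,
        has_transit_route = ed$has_transit_route))$rating

      date <- as.Date(paste0(y, "-01-01")) +
        sample.int(if (y %% 4 == 0) 366L else 365L, n, replace = TRUE) - 1L
      hh <- floor(cv$time_of_day)
      mm <- floor((cv$time_of_day - hh) * 60)
      datetime <- sprintf("%sT%02d:%02d:00", format(date, "%Y-%m-%d"), hh, mm)
      weekday <- weekdays(date, abbreviate = FALSE)

      df <- data.frame(
        x = pts[, 1], y = pts[, 2], zone_id = zone_id,
        datetime = datetime, year = y, month = as.integer(format(date, "%m")),
        sex = cv$sex, age = cv$age,
        age_group = as.character(age_to_group(cv$age)),
        vehicle_type = cv$vehicle_type, weekday = weekday,
        time_of_day = cv$time_of_day, slope_pct = cv$slope_pct,
        surface_failures = stats::rpois(n, 5),
        lighting_pct = round(stats::runif(n, 30, 95), 1),
        on_bike_path = ed$has_bike_path,
        transit_presence = ed$has_transit_route,
        n_lanes = ed$lanes, lane_width = ed$lane_width,
        speed_limit = ed$speed_limit,
        lts = lts, lts4 = as.integer(lts == 4L),
        stringsAsFactors = FALSE)

      eta <- risk_eta(df, risk)
      hs <- truth$hotspot_centers
      if (!is.null(hs) && nrow(hs) > 0) {
        for (j in seq_len(nrow(hs))) {
          inside <- (df$x - hs$x[j])^2 + (df$y - hs$y[j])^2 <= hs$radius[j]^2
          eta[inside] <- eta[inside] + log(hs$multiplier[j])
        }
      }
      df$fatal <- stats::rbinom(n, 1, stats::plogis(eta))
      rows[[k]] <- df
    }
    out <- do.call(rbind, rows)
    out <- cbind(event_id = sprintf("c%06d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# Point at arc-length fraction t along a polyline.
point_along_path <- function(coords, t) {
  if (nrow(coords) < 2) return(coords[1, ])
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  target <- t * sum(seg)
  cum <- cumsum(seg)
  i <- which(cum >= target - 1e-12)[1]
  prev <- if (i == 1) 0 else cum[i - 1]
  frac <- if (seg[i] == 0) 0 else (target - prev) / seg[i]
  coords[i, ] + frac * (coords[i + 1, ] - coords[i, ])
}
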