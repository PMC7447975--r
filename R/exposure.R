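# Exposure denominators: bicyclist population and daily bicycle kilometers
# traveled per zone, year, and sex-by-age stratum, from weighted surveys,
# network routing, polygon allocation and stratified interpolation.

#' Horvitz-Thompson bicyclist population per zone, year and stratum
#'
#' Expands the weighted person records of each survey: the population of a
#' zone/sex/age cell is the sum of design weights over bicyclist person
#' records in that cell. Every zone-by-stratum cell of every survey year is
#' present (zero where no records fall).
#'
#' @param surveys list of survey tables (see [generate_surveys()]).
#' @param zone_ids optional character vector of all zone ids to force into
#'   the panel (default: those seen in the surveys).
#' @return exposure panel data.frame: zone_id, year, sex, age_group,
#'   population, provenance = "observed".
#' @export
estimate_population <- function(surveys, zone_ids = NULL) {
  if (length(surveys) == 0) stop("surveys must be non-empty")
  all <- do.call(rbind, lapply(surveys, function(s)
    s[s$kind == "person", c("year", "weight", "sex", "age_group",
                            "home_zone", "is_bicyclist")]))
  if (any(!is.finite(all$weight)) || any(all$weight < 0))
    stop("invalid input: person weights must be finite and non-negative")
  bic <- all[all$is_bicyclist, ]
  zone_ids <- sort(unique(c(zone_ids, all$home_zone)))
  years <- sort(unique(all$year))
  cells <- expand.grid(zone_id = zone_ids, year = years,
                       sex = c("M", "F"), age_group = age_group_levels(),
                       stringsAsFactors = FALSE)
  key <- function(z, y, s, a) paste(z, y, s, a, sep = "\r")
  agg <- tapply(bic$weight,
                key(bic$home_zone, bic$year, bic$sex, bic$age_group), sum)
  pop <- agg[key(cells$zone_id, cells$year, cells$sex, cells$age_group)]
  cells$population <- as.numeric(ifelse(is.na(pop), 0, pop))
  cells$provenance <- "observed"
  cells[order(cells$zone_id, cells$year, cells$sex, cells$age_group), ,
        drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Shortest network path between two zones
#'
#' Routes between the zones' centroids, each snapped to its nearest network
#' node, minimizing total edge length. Among tied shortest paths the
#' lexicographically smallest node-id sequence is returned, so the result
#' is deterministic.
#'
#' @param network a `road_network`.
#' @param zones a `zone_map`.
#' @param origin_zone,dest_zone zone ids.
#' @param graph optional pre-built igraph of the network.
#' @param snap optional named vector of snapped nodes per zone id.
#' @return list: `nodes` (node-id sequence), `coords` (matrix of node
#'   coordinates), `length_km`.
#' @export
shortest_path <- function(network, zones, origin_zone, dest_zone,
                          graph = NULL, snap = NULL) {
  if (is.null(snap)) {
    cents <- zone_centroids(zones)
    snap <- stats::setNames(nearest_node(network, cents$x, cents$y),
                            cents$zone_id)
  }
  from <- snap[[origin_zone]]; to <- snap[[dest_zone]]
  if (is.null(from) || is.null(to)) stop("unknown zone id")
  g <- graph %||% network_graph(network)
  if (from == to) {
    xy <- network$nodes[match(from, network$nodes$node_id), c("x", "y")]
    return(list(nodes = from, coords = matrix(as.numeric(xy), 1, 2),
                length_km = 0))
  }
  d <- igraph::distances(g, v = igraph::V(g), to = to)[, 1]
  names(d) <- igraph::V(g)$name
  if (!is.finite(d[[from]])) stop("no path: endpoints are disconnected")
  # greedy walk: always step to the smallest-id neighbor that stays on a
  # shortest path, yielding the lexicographically smallest node sequence
  path <- from
  cur <- from
  repeat {
    if (cur == to) break
    nb <- igraph::neighbors(g, cur)
    nb_ids <- nb$name
    eids <- igraph::get_edge_ids(g, rbind(rep(match(cur, igraph::V(g)$name),
                                              length(nb)), as.integer(nb)))
    w <- igraph::E(g)$weight[eids]
    ok <- abs(w + d[nb_ids] - d[[cur]]) <= 1e-9 * pmax(1, d[[cur]])
    nxt <- sort(nb_ids[ok])[1]
    path <- c(path, nxt)
    cur <- nxt
  }
  idx <- match(path, network$nodes$node_id)
  coords <- cbind(network$nodes$x[idx], network$nodes$y[idx])
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  list(nodes = path, coords = coords, length_km = sum(seg) / 1000)
}

#' Allocate a path's daily kilometers traveled to zones
#'
#' Splits the path at zone-polygon boundaries and multiplies each in-zone
#' length by the daily trip count. The per-zone kilometers sum exactly to
#' path length times trips (conservation); any length outside the zone
#' cover is reported as an error.
#'
#' @param path result of [shortest_path()] (or any list with a `coords`
#'   polyline matrix in meters).
#' @param n_trips trips per day on the path.
#' @param zones a `zone_map`.
#' @return data.frame: zone_id, length_km, vkmt (km/day); attribute
#'   `total_km` holds the path length.
#' @export
allocate_vkmt <- function(path, n_trips, zones) {
  coords <- path$coords
  if (is.null(coords) || nrow(coords) < 2)
    return(structure(data.frame(zone_id = character(0), length_km = numeric(0),
                                vkmt = numeric(0)), total_km = 0))
  segs <- split_path_by_zones(coords, zones)
  orphan <- attr(segs, "orphan_length")
  total <- sum(sqrt(rowSums((coords[-1, , drop = FALSE] -
                             coords[-nrow(coords), , drop = FALSE])^2)))
  if (orphan > 1e-6 * max(1, total))
    stop(sprintf("path exits the zone cover: %.3f m unallocated", orphan))
  out <- data.frame(zone_id = segs$zone_id, length_km = segs$length / 1000,
                    vkmt = segs$length / 1000 * n_trips,
                    stringsAsFactors = FALSE)
  structure(out[order(out$zone_id), , drop = FALSE], total_km = total / 1000)
}

#' Fill an exposure panel by stratified linear interpolation
#'
#' Within each zone/sex/age stratum series, fills target years by linear
#' interpolation between the two adjacent observed years, and beyond the
#' last observed year by linear extrapolation from the last two observed
#' years (symmetrically, before the first observed year from the first
#' two). Values are clipped at zero; observed cells pass through unchanged.
#'
#' @param panel exposure panel with `provenance == "observed"` rows (from
#'   [estimate_population()] or with a `daily_vkmt` column).
#' @param target_years years the filled panel must cover.
#' @param value_cols which value columns to interpolate.
#' @return panel covering `target_years` with provenance
#'   observed/interpolated/extrapolated per cell.
#' @export
interpolate_panel <- function(panel, target_years,
                              value_cols = intersect(c("population", "daily_vkmt"),
                                                     names(panel))) {
  obs_years <- sort(unique(panel$year))
  if (length(obs_years) < 2)
    stop("insufficient data: need at least 2 observed years")
  strata_cols <- intersect(c("zone_id", "sex", "age_group"), names(panel))
  key <- do.call(paste, c(panel[strata_cols], sep = "\r"))
  ukey <- unique(key)
  years <- sort(unique(c(target_years)))
  prov <- ifelse(years %in% obs_years, "observed",
          ifelse(years > max(obs_years) | years < min(obs_years),
                 "extrapolated", "interpolated"))
  out <- vector("list", length(ukey))
  for (i in seq_along(ukey)) {
    rows <- panel[key == ukey[i], , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    res <- rows[rep(1L, length(years)), strata_cols, drop = FALSE]
    res$year <- years
    for (vc in value_cols) {
      v <- stats::approx(rows$year, rows[[vc]], xout = years, rule = 1)$y
      # linear extrapolation from the two nearest observed years
      lo <- years < min(rows$year); hi <- years > max(rows$year)
      if (any(hi)) {
        n <- nrow(rows)
        sl <- (rows[[vc]][n] - rows[[vc]][n - 1]) /
              (rows$year[n] - rows$year[n - 1])
        v[hi] <- rows[[vc]][n] + sl * (years[hi] - rows$year[n])
      }
      if (any(lo)) {
        sl <- (rows[[vc]][2] - rows[[vc]][1]) / (rows$year[2] - rows$year[1])
        v[lo] <- rows[[vc]][1] + sl * (years[lo] - rows$year[1])
      }
      res[[vc]] <- pmax(0, v)
    }
    res$provenance <- prov
    out[[i]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c(strata_cols, "year", value_cols, "provenance")]
}

#' Total and stratified percent validation error
#'
#' Compares estimated against actual exposure: the total error is
#' `100 * |sum(actual) - sum(estimated)| / sum(actual)`; the stratified
#' error is the unweighted mean of per-group absolute percent errors,
#' excluding (and reporting) groups with zero actual value.
#'
#' @param actual,estimated numeric vectors aligned by group (or single
#'   totals).
#' @return list: `total_pct_error`, `mean_stratified_pct_error`,
#'   `n_groups`, `n_excluded`.
#' @export
validation_error <- function(actual, estimated) {
  if (length(actual) != length(estimated))
    stop("actual and estimated must be aligned")
  if (sum(actual) == 0) stop("undefined denominator: sum(actual) is zero")
  total <- 100 * abs(sum(actual) - sum(estimated)) / sum(actual)
  nz <- actual != 0
  strat <- if (any(nz))
    mean(100 * abs(actual[nz] - estimated[nz]) / actual[nz]) else NA_real_
  list(total_pct_error = total, mean_stratified_pct_error = strat,
       n_groups = sum(nz), n_excluded = sum(!nz))
}

#' Estimate per-zone daily kilometers traveled from survey trip records
#'
#' Expands weighted trip records to daily origin-destination flows, routes
#' each flow over the network, splits each path across zone polygons and
#' accumulates in-zone kilometers times daily trips.
#'
#' @param surveys list of survey tables.
#' @param zones a `zone_map`.
#' @param network a `road_network`.
#' @return data.frame: zone_id, year, daily_vkmt, provenance = "observed"
#'   (years with trip records only).
#' @export
estimate_vkmt <- function(surveys, zones, network) {
  trips <- do.call(rbind, lapply(surveys, function(s) s[s$kind == "trip", ]))
  if (nrow(trips) == 0) stop("no trip records in surveys")
  cents <- zone_centroids(zones)
  snap <- stats::setNames(nearest_node(network, cents$x, cents$y),
                          cents$zone_id)
  g <- network_graph(network)
  key <- paste(trips$origin_zone, trips$dest_zone)
  flows <- stats::aggregate(weight ~ year + origin_zone + dest_zone,
                            data = trips, FUN = sum)
  ukey <- unique(paste(flows$origin_zone, flows$dest_zone))
  seg_cache <- list()
  zone_ids <- cents$zone_id
  acc <- list()
  for (i in seq_len(nrow(flows))) {
    k <- paste(flows$origin_zone[i], flows$dest_zone[i])
    if (is.null(seg_cache[[k]])) {
      p <- shortest_path(network, zones, flows$origin_zone[i],
                         flows$dest_zone[i], graph = g, snap = snap)
      seg_cache[[k]] <- if (p$length_km > 0)
        split_path_by_zones(p$coords, zones) else
        data.frame(zone_id = character(0), length = numeric(0))
    }
    segs <- seg_cache[[k]]
    if (nrow(segs) == 0) next
    yk <- as.character(flows$year[i])
    if (is.null(acc[[yk]])) acc[[yk]] <- stats::setNames(
      numeric(length(zone_ids)), zone_ids)
    acc[[yk]][segs$zone_id] <- acc[[yk]][segs$zone_id] +
      segs$length / 1000 * flows$weight[i]
  }
  out <- do.call(rbind, lapply(names(acc), function(yk) {
    data.frame(zone_id = zone_ids, year = as.integer(yk),
               daily_vkmt = as.numeric(acc[[yk]][zone_ids]),
               provenance = "observed", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
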