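# Synthetic city: planning zones and a road network.

#' Generate a synthetic city: zone map and road network
#'
#' Builds a tessellation of planning zones (Voronoi cells of uniformly
#' seeded points by default, or a rectangular grid) over a rectangular
#' study window, plus a lattice road network covering the window. Zone
#' polygons are valid, interior-disjoint and jointly tile the window;
#' the network is connected and every zone centroid has a nearby node.
#'
#' @param n_zones number of zones (>= 4).
#' @param window numeric length-4 `c(xmin, ymin, xmax, ymax)` in meters.
#' @param seed integer seed; identical calls are byte-identical.
#' @param tessellation "voronoi" (default) or "grid".
#' @param lattice_k nodes per axis of the road lattice; default scales with
#'   `sqrt(n_zones)`.
#' @return list with components `zones` (a `zone_map`: list of
#'   `zone_id`/`polygon`/`income_stratum`, plus the window) and `network`
#'   (a `road_network`: `nodes` and `edges` data frames).
#' @examples
#' city <- generate_city(n_zones = 9, window = c(0, 0, 3000, 3000), seed = 1)
#' sum(vapply(city$zones$zones, function(z) polygon_area(z$polygon), 1)) / 1e6
#' @export
generate_city <- function(n_zones, window = c(0, 0, 20000, 20000), seed = 1L,
                          tessellation = c("voronoi", "grid"),
                          lattice_k = NULL) {
  tessellation <- match.arg(tessellation)
  if (!is.numeric(n_zones) || n_zones < 4)
    stop("n_zones must be at least 4")
  if (length(window) != 4 || window[3] <= window[1] || window[4] <= window[2])
    stop("window must be c(xmin, ymin, xmax, ymax) with positive area")

  with_seed(seed, {
    polys <- switch(tessellation,
      voronoi = {
        # rejection-free uniform sites; re-draw pathological near-duplicates
        sites <- cbind(stats::runif(n_zones, window[1], window[3]),
                       stats::runif(n_zones, window[2], window[4]))
        voronoi_cells(sites, window)
      },
      grid = grid_cells(n_zones, window))
    ids <- sprintf("Z%03d", seq_len(n_zones))
    strat <- sample(c("low", "middle", "high"), n_zones, replace = TRUE,
                    prob = c(0.45, 0.40, 0.15))
    zones <- structure(list(
      zones = lapply(seq_len(n_zones), function(i)
        list(zone_id = ids[i], polygon = polys[[i]],
             income_stratum = strat[i])),
      window = window), class = "zone_map")

    k <- lattice_k %||% max(5L, ceiling(sqrt(n_zones)) + 2L)
    network <- lattice_network(window, k)
    list(zones = zones, network = network)
  })
}

# Exact-count rectangular grid tessellation: rows of equal height, each row
# split into equal cells; row cell counts differ by at most one.
grid_cells <- function(n_zones, window) {
  nr <- max(2L, floor(sqrt(n_zones)))
  base <- n_zones %/% nr
  extra <- n_zones %% nr
  per_row <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))
  h <- (window[4] - window[2]) / nr
  out <- list()
  for (r in seq_len(nr)) {
    w <- (window[3] - window[1]) / per_row[r]
    y0 <- window[2] + (r - 1) * h
    for (cidx in seq_len(per_row[r])) {
      x0 <- window[1] + (cidx - 1) * w
      out[[length(out) + 1L]] <- rect_polygon(c(x0, y0, x0 + w, y0 + h))
    }
  }
  out
}

# Regular k x k lattice with street-like edge attributes.
lattice_network <- function(window, k) {
  xs <- seq(window[1], window[3], length.out = k)
  ys <- seq(window[2], window[4], length.out = k)
  nodes <- data.frame(
    node_id = sprintf("n%04d", seq_len(k * k)),
    x = rep(xs, times = k), y = rep(ys, each = k),
    stringsAsFactors = FALSE)
  a <- integer(0); b <- integer(0)
  idx <- function(ix, iy) (iy - 1L) * k + ix
  for (iy in seq_len(k)) for (ix in seq_len(k)) {
    if (ix < k) { a <- c(a, idx(ix, iy)); b <- c(b, idx(ix + 1L, iy)) }
    if (iy < k) { a <- c(a, idx(ix, iy)); b <- c(b, idx(ix, iy + 1L)) }
  }
  len <- sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2)
  m <- length(a)
  edges <- data.frame(
    edge_id = sprintf("e%05d", seq_len(m)),
    node_a = nodes$node_id[a], node_b = nodes$node_id[b],
    length = len,
    lanes = sample(1:4, m, replace = TRUE, prob = c(0.25, 0.4, 0.25, 0.1)),
    lane_width = round(stats::runif(m, 2.7, 4.8), 2),
    speed_limit = sample(c(30, 40, 50, 60, 80), m, replace = TRUE,
                         prob = c(0.25, 0.25, 0.3, 0.15, 0.05)),
    has_bike_path = stats::rbinom(m, 1, 0.12),
    has_transit_route = stats::rbinom(m, 1, 0.30),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' Build the igraph representation of a road network
#' @param network a `road_network`.
#' @return an igraph object with edge attribute `weight` = length (m).
#' @export
network_graph <- function(network) {
  igraph::graph_from_data_frame(
    data.frame(from = network$edges$node_a, to = network$edges$node_b,
               weight = network$edges$length),
    directed = FALSE,
    vertices = network$nodes$node_id)
}

#' Nearest network node to a point
#' @param network a `road_network`.
#' @param x,y point coordinates (vectors).
#' @return character vector of node ids.
#' @export
nearest_node <- function(network, x, y) {
  vapply(seq_along(x), function(i) {
    d2 <- (network$nodes$x - x[i])^2 + (network$nodes$y - y[i])^2
    network$nodes$node_id[which.min(d2)]
  }, character(1))
}

#' Zone centroids of a zone map
#' @param zones a `zone_map`.
#' @return data.frame with zone_id, x, y.
#' @export
zone_centroids <- function(zones) {
  cents <- t(vapply(zones$zones, function(z) polygon_centroid(z$polygon),
                    numeric(2)))
  data.frame(zone_id = vapply(zones$zones, `[[`, character(1), "zone_id"),
             x = cents[, 1], y = cents[, 2], stringsAsFactors = FALSE)
}
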