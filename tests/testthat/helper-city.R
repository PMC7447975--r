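# Shared synthetic-city fixtures, built once per test run and memoised.
# The small city keeps the unit tests fast; the full-scale city matches
# the generator defaults and backs the recovery checks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_city <- function() memo("small_city", function()
  generate_city(25, c(0, 0, 10000, 10000), seed = 3))

small_truth <- function() memo("small_truth", function()
  make_ground_truth(small_city(), seed = 3, n_od = 200))

small_null_truth <- function() memo("small_null_truth", function() {
  tr <- make_ground_truth(small_city(), seed = 3, n_od = 200,
                          hotspot_multiplier = 1)
  tr$risk <- null_risk()
  tr
})

full_city <- function() memo("full_city", function()
  generate_city(100, c(0, 0, 20000, 20000), seed = 5))

full_truth <- function() memo("full_truth", function()
  make_ground_truth(full_city(), seed = 5))

# brute-force shortest path by exhaustive Bellman-Ford relaxation;
# independent of the package's igraph-based routing
bf_shortest <- function(nodes, edges, from, to) {
  d <- stats::setNames(rep(Inf, nrow(nodes)), nodes$node_id)
  d[from] <- 0
  for (it in seq_len(nrow(nodes))) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$node_a[i]; b <- edges$node_b[i]; w <- edges$length[i]
      if (d[a] + w < d[b]) d[b] <- d[a] + w
      if (d[b] + w < d[a]) d[a] <- d[b] + w
    }
  }
  unname(d[to])
}

# dense point-sampling oracle for path-to-zone allocation: sample many
# points along the polyline, assign by point-in-polygon, scale lengths
sampling_alloc_oracle <- function(coords, zones, n_pts = 10000) {
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  total <- sum(seg)
  t <- (seq_len(n_pts) - 0.5) / n_pts
  cum <- cumsum(seg) / total
  pts <- t(vapply(t, function(ti) {
    i <- which(cum >= ti - 1e-12)[1]
    prev <- if (i == 1) 0 else cum[i - 1]
    frac <- (ti - prev) / (cum[i] - prev)
    coords[i, ] + frac * (coords[i + 1, ] - coords[i, ])
  }, numeric(2)))
  zid <- locate_zone(pts[, 1], pts[, 2], zones, tol = 1e-6)
  tab <- table(zid)
  data.frame(zone_id = names(tab),
             length = as.numeric(tab) * total / n_pts,
             stringsAsFactors = FALSE)
}

# naive per-cell Gaussian summation oracle for the kernel surface
naive_kde_oracle <- function(pattern, sigma, xs, ys) {
  z <- matrix(0, length(xs), length(ys))
  n <- length(pattern$x)
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    s <- 0
    for (k in seq_len(n)) {
      s <- s + exp(-((xs[i] - pattern$x[k])^2 + (ys[j] - pattern$y[k])^2) /
                     (2 * sigma^2)) / (2 * pi * sigma^2)
    }
    z[i, j] <- s / n
  }
  z
}
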