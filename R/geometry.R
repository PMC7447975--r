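# Planar polygon primitives used throughout the pipeline.
#
# Polygons are numeric matrices with columns x, y holding an open ring
# (the last vertex is not repeated). All coordinates are meters in a
# planar metric CRS.

#' Signed and absolute polygon area
#'
#' Shoelace formula. `polygon_area()` returns the absolute area in square
#' meters; `polygon_area_signed()` keeps the orientation sign (positive for
#' counter-clockwise rings).
#'
#' @param poly numeric matrix with columns x, y (open ring).
#' @return area in m^2.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' @rdname polygon_area
#' @export
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon centroid
#' @param poly numeric matrix with columns x, y (open ring).
#' @return numeric length-2 (x, y) centroid of the polygon interior.
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Point-in-polygon test (even-odd rule, boundary-inclusive)
#'
#' Vectorized over points. A point within `tol` meters of an edge counts as
#' inside, so shared zone boundaries never orphan a point.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param poly polygon matrix (open ring).
#' @param tol boundary tolerance in meters.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- logical(length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  jj <- c(n, seq_len(n - 1L))
  for (k in seq_len(n)) {
    xi <- xs[k]; yi <- ys[k]; xj <- xs[jj[k]]; yj <- ys[jj[k]]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- (xj - xi) * (py[crosses] - yi) / (yj - yi) + xi
      flip <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  if (tol > 0) {
    border <- !inside
    if (any(border)) {
      inside[border] <- inside[border] |
        point_on_boundary(px[border], py[border], poly, tol)
    }
  }
  inside
}

#' Distance-based boundary membership
#' @inheritParams point_in_polygon
#' @return logical vector: point lies within `tol` of some polygon edge.
#' @export
point_on_boundary <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  hit <- logical(length(px))
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    ax <- poly[k, 1]; ay <- poly[k, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    hit <- hit | (dx * dx + dy * dy <= tol * tol)
  }
  hit
}

#' Clip a convex or simple polygon by a half-plane
#'
#' Sutherland-Hodgman step keeping the region where
#' `a*x + b*y + c <= 0`.
#'
#' @param poly polygon matrix (open ring).
#' @param a,b,c half-plane coefficients.
#' @return clipped polygon matrix (possibly with 0 rows).
#' @export
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] + c
  keep <- d <= 0
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    if (keep[k]) out <- rbind(out, poly[k, ])
    if (keep[k] != keep[j]) {
      t <- d[k] / (d[k] - d[j])
      out <- rbind(out, poly[k, ] + t * (poly[j, ] - poly[k, ]))
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Voronoi tessellation of a rectangle
#'
#' Computes each site's Voronoi cell as the intersection of the window with
#' the perpendicular-bisector half-planes against every other site. O(n^2)
#' but exact; intended for up to a few hundred zones.
#'
#' @param sites matrix of site coordinates (columns x, y).
#' @param window numeric length-4 `c(xmin, ymin, xmax, ymax)`.
#' @return list of polygon matrices, one per site, jointly tiling the window.
#' @export
voronoi_cells <- function(sites, window) {
  rect <- rect_polygon(window)
  n <- nrow(sites)
  lapply(seq_len(n), function(i) {
    cell <- rect
    for (j in seq_len(n)) {
      if (j == i || nrow(cell) == 0L) next
      # bisector half-plane: points closer to site i than site j
      mx <- (sites[i, 1] + sites[j, 1]) / 2
      my <- (sites[i, 2] + sites[j, 2]) / 2
      a <- sites[j, 1] - sites[i, 1]
      b <- sites[j, 2] - sites[i, 2]
      cell <- clip_halfplane(cell, a, b, -(a * mx + b * my))
    }
    cell
  })
}

#' Rectangle as a polygon ring
#' @param window numeric length-4 `c(xmin, ymin, xmax, ymax)`.
#' @return 4-row polygon matrix (counter-clockwise open ring).
#' @export
rect_polygon <- function(window) {
  m <- matrix(c(window[1], window[2],
                window[3], window[2],
                window[3], window[4],
                window[1], window[4]), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Locate points in a zone map
#'
#' Assigns each point to the zone whose polygon contains it. A point on a
#' shared boundary is assigned to the lexicographically smallest zone_id so
#' assignment is deterministic.
#'
#' @param px,py point coordinates.
#' @param zones a `zone_map` (see [generate_city()]) or plain list with
#'   `zone_id` and `polygon` entries.
#' @param tol boundary tolerance in meters.
#' @return character vector of zone ids (`NA` where no zone contains the point).
#' @export
locate_zone <- function(px, py, zones, tol = 1e-9) {
  ids <- vapply(zones$zones, `[[`, character(1), "zone_id")
  ord <- order(ids)
  out <- rep(NA_character_, length(px))
  todo <- rep(TRUE, length(px))
  for (k in ord) {
    if (!any(todo)) break
    z <- zones$zones[[k]]
    bb <- apply(z$polygon, 2, range)
    cand <- todo &
      px >= bb[1, 1] - tol & px <= bb[2, 1] + tol &
      py >= bb[1, 2] - tol & py <= bb[2, 2] + tol
    if (!any(cand)) next
    hit <- point_in_polygon(px[cand], py[cand], z$polygon, tol)
    idx <- which(cand)[hit]
    out[idx] <- z$zone_id
    todo[idx] <- FALSE
  }
  out
}

# Parameter values t in (0,1) where segment p0->p1 crosses an edge of poly.
segment_crossings <- function(p0, p1, poly) {
  n <- nrow(poly)
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  ts <- numeric(0)
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    ex <- poly[j, 1] - poly[k, 1]; ey <- poly[j, 2] - poly[k, 2]
    denom <- dx * ey - dy * ex
    if (abs(denom) < .Machine$double.eps) next
    t <- ((poly[k, 1] - p0[1]) * ey - (poly[k, 2] - p0[2]) * ex) / denom
    u <- ((poly[k, 1] - p0[1]) * dy - (poly[k, 2] - p0[2]) * dx) / denom
    if (t > 1e-12 && t < 1 - 1e-12 && u >= -1e-12 && u <= 1 + 1e-12)
      ts <- c(ts, t)
  }
  ts
}

#' Split a polyline by zone boundaries
#'
#' Cuts every segment of the polyline at each zone-boundary crossing and
#' assigns each resulting piece to the zone containing its midpoint
#' (boundary ties go to the lexicographically smallest zone_id). Total
#' length is conserved exactly: the pieces are a partition of the path.
#'
#' @param coords polyline matrix with columns x, y (node coordinates, meters).
#' @param zones a `zone_map`.
#' @return data.frame with `zone_id` and `length` (meters) per piece,
#'   aggregated by zone; attribute `orphan_length` holds any length that fell
#'   outside the zone cover.
#' @export
split_path_by_zones <- function(coords, zones) {
  pieces_zone <- character(0)
  pieces_len <- numeric(0)
  bb <- lapply(zones$zones, function(z) apply(z$polygon, 2, range))
  for (s in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[s, ]; p1 <- coords[s + 1L, ]
    seglen <- sqrt(sum((p1 - p0)^2))
    if (seglen == 0) next
    sx <- range(p0[1], p1[1]); sy <- range(p0[2], p1[2])
    ts <- c(0, 1)
    for (zi in seq_along(zones$zones)) {
      b <- bb[[zi]]
      if (sx[2] < b[1, 1] || sx[1] > b[2, 1] ||
          sy[2] < b[1, 2] || sy[1] > b[2, 2]) next
      ts <- c(ts, segment_crossings(p0, p1, zones$zones[[zi]]$polygon))
    }
    ts <- sort(unique(pmin(1, pmax(0, ts))))
    for (q in seq_len(length(ts) - 1L)) {
      tm <- (ts[q] + ts[q + 1L]) / 2
      mx <- p0[1] + tm * (p1[1] - p0[1])
      my <- p0[2] + tm * (p1[2] - p0[2])
      zid <- locate_zone(mx, my, zones, tol = 1e-6)
      pieces_zone <- c(pieces_zone, zid)
      pieces_len <- c(pieces_len, (ts[q + 1L] - ts[q]) * seglen)
    }
  }
  orphan <- sum(pieces_len[is.na(pieces_zone)])
  keep <- !is.na(pieces_zone)
  agg <- tapply(pieces_len[keep], pieces_zone[keep], sum)
  out <- data.frame(zone_id = names(agg), length = as.numeric(agg),
                    stringsAsFactors = FALSE)
  attr(out, "orphan_length") <- orphan
  out
}
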