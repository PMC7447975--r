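# Spatial hotspot detection for fatal collisions: Ripley's K with
# Monte-Carlo envelopes, Gaussian kernel density surfaces with
# likelihood-cross-validated bandwidth, highest-density-region contours,
# quadrat dispersion tests and a top-fraction flagging rule.

#' Planar point pattern
#' @param x,y event coordinates in meters.
#' @param window numeric length-4 `c(xmin, ymin, xmax, ymax)`.
#' @return a `point_pattern` list.
#' @export
point_pattern <- function(x, y, window) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (any(x < window[1] | x > window[3] | y < window[2] | y > window[4]))
    stop("all points must lie inside the window")
  structure(list(x = x, y = y, window = window,
                 area = (window[3] - window[1]) * (window[4] - window[2])),
            class = "point_pattern")
}

#' Ripley's K function
#'
#' `K(r) = |W| / (n (n-1)) * sum_{i != j} e_ij 1(d_ij <= r)`, with
#' translation edge-correction weights
#' `e_ij = |W| / ((a - |dx|)(b - |dy|))` for a rectangular window, or
#' `e_ij = 1` with `correction = "none"`. Under complete spatial
#' randomness K(r) is pi r^2.
#'
#' @param pattern a `point_pattern` with n >= 2.
#' @param radii increasing radii (m), below half the window diameter.
#' @return data.frame: r, k (estimate), k_csr (`pi r^2`).
#' @param correction "translation" or "none".
#' @export
ripleys_k <- function(pattern, radii, correction = c("translation", "none")) {
  correction <- match.arg(correction)
  n <- length(pattern$x)
  if (n < 2) stop("insufficient points: Ripley's K needs n >= 2")
  win <- pattern$window
  a <- win[3] - win[1]; b <- win[4] - win[2]
  if (any(radii >= sqrt(a^2 + b^2) / 2))
    stop("radii must be below half the window diameter")
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  d <- sqrt(dx^2 + dy^2)
  w <- if (correction == "translation")
    pattern$area / ((a - dx) * (b - dy)) else matrix(1, n, n)
  diag(w) <- 0
  k <- vapply(radii, function(r)
    pattern$area / (n * (n - 1)) * sum(w[d <= r & row(d) != col(d)]), 1)
  data.frame(r = radii, k = k, k_csr = pi * radii^2)
}

#' Monte-Carlo envelope of Ripley's K under complete spatial randomness
#'
#' Simulates `n_sim` uniform patterns with the same n and window and
#' returns the pointwise 2.5%-97.5% envelope of K; clustering is declared
#' at radii where the observed K exceeds the upper envelope.
#'
#' @inheritParams ripleys_k
#' @param n_sim number of simulations (>= 39).
#' @param seed integer seed.
#' @return data.frame: r, k_obs, lo, hi, clustered (logical).
#' @export
csr_envelope <- function(pattern, radii, n_sim = 199, seed = 1L,
                         correction = c("translation", "none")) {
  correction <- match.arg(correction)
  if (n_sim < 39) stop("n_sim must be at least 39")
  n <- length(pattern$x)
  win <- pattern$window
  obs <- ripleys_k(pattern, radii, correction)$k
  sims <- with_seed(seed, vapply(seq_len(n_sim), function(s) {
    p <- point_pattern(stats::runif(n, win[1], win[3]),
                       stats::runif(n, win[2], win[4]), win)
    ripleys_k(p, radii, correction)$k
  }, numeric(length(radii))))
  sims <- matrix(sims, nrow = length(radii))
  lo <- apply(sims, 1, stats::quantile, 0.025)
  hi <- apply(sims, 1, stats::quantile, 0.975)
  data.frame(r = radii, k_obs = obs, lo = lo, hi = hi, clustered = obs > hi)
}

#' Gaussian kernel density surface
#'
#' Fixed-bandwidth isotropic Gaussian kernel estimate: an equal-weight
#' Gaussian mixture centered on the points,
#' `f(u) = (1/n) sum_i N(u; (x_i, y_i), sigma^2 I)`, evaluated at the
#' centers of a regular raster over the window.
#'
#' @param pattern a `point_pattern`.
#' @param sigma bandwidth (m), > 0.
#' @param grid_res raster cell side (m).
#' @return a `risk_surface` list: `xs`, `ys` (cell-center coordinates),
#'   `z` (density matrix, rows follow `xs`), `sigma`, `cell_area`,
#'   `window`, `n`.
#' @export
kde_surface <- function(pattern, sigma, grid_res) {
  if (sigma <= 0) stop("sigma must be positive")
  win <- pattern$window
  xs <- seq(win[1] + grid_res / 2, win[3], by = grid_res)
  ys <- seq(win[2] + grid_res / 2, win[4], by = grid_res)
  gx <- stats::dnorm(outer(xs, pattern$x, "-"), sd = sigma)
  gy <- stats::dnorm(outer(ys, pattern$y, "-"), sd = sigma)
  z <- gx %*% t(gy) / length(pattern$x)
  structure(list(xs = xs, ys = ys, z = z, sigma = sigma,
                 cell_area = grid_res^2, window = win,
                 n = length(pattern$x)),
            class = "risk_surface")
}

#' Probability mass of a density surface inside its window
#' @param surface a `risk_surface`.
#' @return numeric scalar (Riemann sum of density times cell area).
#' @export
surface_mass <- function(surface) sum(surface$z) * surface$cell_area

#' Leave-one-out cross-validated kernel bandwidth
#'
#' Selects the bandwidth maximizing the leave-one-out point-process
#' log-likelihood `sum_i log f_{-i}(x_i)`; ties prefer the smallest
#' bandwidth. Optionally refines around the best grid candidate by
#' golden-section search.
#'
#' @param pattern a `point_pattern` with >= 2 distinct points.
#' @param sigma_candidates candidate bandwidths (m), bounded away from 0;
#'   default a log-spaced grid from 10 m to 5 km.
#' @param refine golden-section refinement between the best candidate's
#'   neighbors.
#' @return list: `sigma` (selected), `loglik` (per candidate), `candidates`.
#' @export
loocv_bandwidth <- function(pattern,
                            sigma_candidates = exp(seq(log(10), log(5000),
                                                       length.out = 24)),
                            refine = TRUE) {
  if (length(sigma_candidates) == 0) stop("empty candidate list")
  xy <- cbind(pattern$x, pattern$y)
  if (nrow(unique(xy)) < 2) stop("need at least 2 distinct points")
  d2 <- as.matrix(stats::dist(xy))^2
  n <- nrow(xy)
  loo_ll <- function(s) {
    k <- exp(-d2 / (2 * s^2)) / (2 * pi * s^2)
    diag(k) <- 0
    f <- rowSums(k) / (n - 1)
    if (any(f <= 0)) -Inf else sum(log(f))
  }
  ll <- vapply(sigma_candidates, loo_ll, 1)
  if (all(!is.finite(ll)))
    stop("bandwidth failure: all candidates give -Inf leave-one-out likelihood")
  ord <- order(sigma_candidates)
  sc <- sigma_candidates[ord]; ll <- ll[ord]
  best <- which(ll == max(ll))[1]   # ties -> smallest sigma
  sigma <- sc[best]
  if (refine && length(sc) > 1) {
    lo <- if (best > 1) sc[best - 1] else sc[best]
    hi <- if (best < length(sc)) sc[best + 1] else sc[best]
    if (hi > lo) {
      opt <- stats::optimize(function(s) loo_ll(s), c(lo, hi), maximum = TRUE,
                             tol = (hi - lo) * 1e-3)
      if (opt$objective > max(ll)) sigma <- opt$maximum
    }
  }
  list(sigma = sigma, loglik = ll, candidates = sc)
}

#' Highest-density region of a kernel surface
#'
#' Thresholds the raster at the largest density `t` such that cells with
#' `f >= t` hold at least `mass` of the surface's total mass, and splits
#' the selected cells into 4-connected components.
#'
#' @param surface a `risk_surface`.
#' @param mass probability mass to enclose (default 0.95).
#' @return list: `threshold`, `cells` (ix, iy, x, y, density, component),
#'   `components` (component, n_cells, area_m2), `mass`.
#' @export
contour_region <- function(surface, mass = 0.95) {
  tot <- sum(surface$z)
  if (!is.finite(tot) || tot <= 0) stop("invalid surface: no positive mass")
  z <- surface$z
  ord <- order(z, decreasing = TRUE)
  if (mass >= 1) {
    # the whole support: every cell with positive density
    ncell <- sum(z > 0)
  } else {
    cum <- cumsum(z[ord]) / tot
    ncell <- which(cum >= mass)[1]
    if (is.na(ncell)) ncell <- length(ord)
  }
  sel <- ord[seq_len(ncell)]
  threshold <- z[ord[ncell]]
  nx <- length(surface$xs); ny <- length(surface$ys)
  ix <- ((sel - 1) %% nx) + 1L
  iy <- ((sel - 1) %/% nx) + 1L
  # 4-connected component labelling by repeated flood fill
  lab <- matrix(0L, nx, ny)
  lab[cbind(ix, iy)] <- -1L
  comp <- 0L
  for (s in seq_along(ix)) {
    if (lab[ix[s], iy[s]] != -1L) next
    comp <- comp + 1L
    queue <- list(c(ix[s], iy[s]))
    lab[ix[s], iy[s]] <- comp
    while (length(queue)) {
      c0 <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nx2 <- c0[1] + dd[1]; ny2 <- c0[2] + dd[2]
        if (nx2 >= 1 && nx2 <= nx && ny2 >= 1 && ny2 <= ny &&
            lab[nx2, ny2] == -1L) {
          lab[nx2, ny2] <- comp
          queue[[length(queue) + 1L]] <- c(nx2, ny2)
        }
      }
    }
  }
  cells <- data.frame(ix = ix, iy = iy,
                      x = surface$xs[ix], y = surface$ys[iy],
                      density = z[sel], component = lab[cbind(ix, iy)])
  comps <- stats::aggregate(list(n_cells = cells$component),
                            by = list(component = cells$component), FUN = length)
  comps$area_m2 <- comps$n_cells * surface$cell_area
  list(threshold = threshold, cells = cells, components = comps, mass = mass)
}

#' Quadrat-count dispersion test
#'
#' Tiles the window with square quadrats of the given side (edge quadrats
#' clipped to the window, with expectations proportional to their true
#' clipped area), counts events per quadrat with half-open membership
#' (last row/column closed), and tests departure from complete spatial
#' randomness with the chi-square index of dispersion
#' `X^2 = sum (n_i - E_i)^2 / E_i`, df = #quadrats - 1, upper-tail p.
#'
#' @param pattern a `point_pattern`.
#' @param side quadrat side (m), > 0.
#' @return a `quadrat_grid` list: `quadrats` (id, x0, y0, x1, y1, area_km2,
#'   count, rate per km^2), `side`, `statistic`, `df`, `p_value`, `n`.
#' @export
quadrat_test <- function(pattern, side) {
  if (side <= 0) stop("side must be positive")
  win <- pattern$window
  w <- win[3] - win[1]; h <- win[4] - win[2]
  nx <- max(1L, ceiling(w / side)); ny <- max(1L, ceiling(h / side))
  if (nx * ny < 2) stop("invalid grid: fewer than 2 quadrats")
  ix <- pmin(floor((pattern$x - win[1]) / side), nx - 1)
  iy <- pmin(floor((pattern$y - win[2]) / side), ny - 1)
  counts <- matrix(0, nx, ny)
  for (i in seq_along(ix)) counts[ix[i] + 1, iy[i] + 1] <-
    counts[ix[i] + 1, iy[i] + 1] + 1
  grid <- expand.grid(gx = seq_len(nx), gy = seq_len(ny))
  x0 <- win[1] + (grid$gx - 1) * side
  y0 <- win[2] + (grid$gy - 1) * side
  x1 <- pmin(x0 + side, win[3]); y1 <- pmin(y0 + side, win[4])
  area <- (x1 - x0) * (y1 - y0)
  cnt <- counts[cbind(grid$gx, grid$gy)]
  n <- length(pattern$x)
  e <- n * area / sum(area)
  x2 <- sum((cnt - e)^2 / e)
  df <- length(cnt) - 1L
  quadrats <- data.frame(
    id = sprintf("q%04d", seq_along(cnt)),
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    area_km2 = area / 1e6, count = cnt, rate = cnt / (area / 1e6),
    stringsAsFactors = FALSE)
  structure(list(quadrats = quadrats, side = side, statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE), n = n),
            class = "quadrat_grid")
}

#' Flag the top-fraction high-risk quadrats
#'
#' Returns the quadrats at or above the `1 - fraction` quantile of the
#' event rate per square kilometer; ties at the cutoff are all included.
#' Output is sorted by rate, descending.
#'
#' @param grid a `quadrat_grid`.
#' @param fraction top fraction to flag (default 0.05).
#' @return data.frame of flagged quadrats (columns of `grid$quadrats` plus
#'   `cutoff` attribute); a warning is issued when all rates are tied.
#' @export
top_risk_areas <- function(grid, fraction = 0.05) {
  q <- grid$quadrats
  k <- max(1L, ceiling(fraction * nrow(q)))
  cutoff <- sort(q$rate, decreasing = TRUE)[k]
  if (length(unique(q$rate)) == 1L)
    warning("all quadrat rates are equal; flagging everything")
  out <- q[q$rate >= cutoff, , drop = FALSE]
  out <- out[order(-out$rate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Full hotspot-detection pipeline for one point pattern
#'
#' Chains bandwidth selection, the kernel surface, the 95% highest-density
#' region, the quadrat grid (side = square root of the smallest HDR
#' component's area, unless overridden) and the top-fraction rule.
#'
#' @param pattern a `point_pattern`.
#' @param mass HDR mass (default 0.95).
#' @param fraction top flagging fraction (default 0.05).
#' @param grid_res kernel raster resolution (m); default window width/128.
#' @param side quadrat side override (m); default from the HDR rule.
#' @param sigma bandwidth override (m); default cross-validated.
#' @return list: `bandwidth`, `surface`, `hdr`, `grid`, `flagged`.
#' @export
detect_hotspots <- function(pattern, mass = 0.95, fraction = 0.05,
                            grid_res = NULL, side = NULL, sigma = NULL) {
  win <- pattern$window
  grid_res <- grid_res %||% ((win[3] - win[1]) / 128)
  if (is.null(sigma)) {
    bw <- loocv_bandwidth(pattern)
    sigma <- bw$sigma
  } else bw <- list(sigma = sigma)
  surface <- kde_surface(pattern, sigma, grid_res)
  hdr <- contour_region(surface, mass)
  # grid size from the kernel's significant-cluster scale, rounded so the
  # quadrats tile the window in equal rectangles (no clipped slivers whose
  # tiny areas would dominate the rate ranking)
  # grid side from the kernel's significant-cluster scale: an isolated
  # kernel cluster's 95% contour is a disk of radius
  # sigma*sqrt(2 ln(1/(1-mass))) (2.45 sigma at 95%), so a quadrat of that
  # side lets a cluster span a few quadrats with a clear peak. (The area
  # of the smallest HDR component is not used: a single-cell island would
  # collapse the grid.) Bounds: at least 5x5 quadrats (a top-5% rule
  # needs a grid) and at most 32x32 (counts must not be mostly zero)
  side <- side %||% {
    s0 <- sigma * sqrt(2 * log(1 / (1 - mass)))
    w <- win[3] - win[1]
    w / min(32, max(5, round(w / s0)))
  }
  grid <- quadrat_test(pattern, side)
  flagged <- top_risk_areas(grid, fraction)
  list(bandwidth = bw, surface = surface, hdr = hdr, grid = grid,
       flagged = flagged)
}
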