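test_that("Ripley's K matches hand-computed pair counts on toy patterns", {
  # three collinear points in the unit square: 4 ordered pairs within 0.15
  pat <- point_pattern(c(0, 0, 0), c(0, 0.1, 0.2), c(0, 0, 1, 1))
  k <- ripleys_k(pat, c(0.05, 0.15), correction = "none")
  expect_equal(k$k[1], 0)                     # no pairs within 0.05
  expect_equal(k$k[2], 4 / 6, tolerance = 1e-12)
  # r = 0 has no pairs
  expect_equal(ripleys_k(pat, 1e-12, correction = "none")$k, 0)
  expect_error(ripleys_k(point_pattern(0.5, 0.5, c(0, 0, 1, 1)), 0.1),
               "insufficient points")
})

test_that("K is monotone in r and near pi r^2 under complete spatial randomness", {
  set.seed(8)
  pat <- point_pattern(runif(200), runif(200), c(0, 0, 1, 1))
  radii <- seq(0.02, 0.2, by = 0.02)
  k <- ripleys_k(pat, radii)
  expect_true(all(diff(k$k) >= 0))
  env <- csr_envelope(pat, radii, n_sim = 99, seed = 1)
  expect_lt(mean(k$k > env$hi), 0.3)
  # envelopes are reproducible from the seed
  env2 <- csr_envelope(pat, radii, n_sim = 99, seed = 1)
  expect_identical(env, env2)
})

test_that("planted clusters push K above the CSR envelope at the cluster scale", {
  set.seed(15)
  cx <- rep(c(2000, 7000), each = 60) + rnorm(120, 0, 300)
  cy <- rep(c(3000, 8000), each = 60) + rnorm(120, 0, 300)
  bg <- cbind(runif(60, 0, 10000), runif(60, 0, 10000))
  pat <- point_pattern(pmin(pmax(c(cx, bg[, 1]), 0), 10000),
                       pmin(pmax(c(cy, bg[, 2]), 0), 10000),
                       c(0, 0, 10000, 10000))
  env <- csr_envelope(pat, c(250, 500, 1000), n_sim = 99, seed = 2)
  expect_true(any(env$clustered))
})

test_that("the kernel surface matches the closed form and the naive oracle", {
  win <- c(0, 0, 1000, 1000)
  single <- point_pattern(500, 500, win)
  s <- kde_surface(single, sigma = 50, grid_res = 10)
  peak <- 1 / (2 * pi * 50^2)
  expect_equal(max(s$z), peak, tolerance = 1e-3)
  # two coincident points give the same density as one
  pair <- point_pattern(c(500, 500), c(500, 500), win)
  s2 <- kde_surface(pair, sigma = 50, grid_res = 10)
  expect_equal(s2$z, s$z, tolerance = 1e-14)
  # interior pattern keeps essentially all mass inside the window
  expect_gt(surface_mass(s), 0.98)
  expect_lte(surface_mass(s), 1 + 1e-9)
  # random pattern equals the per-cell double-loop summation
  set.seed(4)
  pat <- point_pattern(runif(15, 100, 900), runif(15, 100, 900), win)
  srf <- kde_surface(pat, sigma = 80, grid_res = 50)
  oracle <- naive_kde_oracle(pat, 80, srf$xs, srf$ys)
  expect_lt(max(abs(srf$z - oracle)), 1e-12)
  expect_error(kde_surface(pat, -1, 50), "positive")
})

test_that("leave-one-out bandwidth selection picks the cluster scale", {
  set.seed(10)
  # two tight clusters: 10 m wins over 10 km when jitter is a few meters
  x <- c(rnorm(20, 1000, 3), rnorm(20, 9000, 3))
  y <- c(rnorm(20, 1000, 3), rnorm(20, 9000, 3))
  pat <- point_pattern(x, y, c(0, 0, 10000, 10000))
  sel <- loocv_bandwidth(pat, sigma_candidates = c(10, 10000), refine = FALSE)
  expect_equal(sel$sigma, 10)
  # grid search against the package's refined search: within grid spacing
  grid <- exp(seq(log(1), log(100), length.out = 60))
  ll <- vapply(grid, function(s) {
    d2 <- as.matrix(stats::dist(cbind(x, y)))^2
    k <- exp(-d2 / (2 * s^2)) / (2 * pi * s^2); diag(k) <- 0
    sum(log(rowSums(k) / (length(x) - 1)))
  }, 1)
  best_grid <- grid[which.max(ll)]
  sel2 <- loocv_bandwidth(pat, sigma_candidates = grid, refine = TRUE)
  expect_lt(abs(log(sel2$sigma) - log(best_grid)), diff(log(grid[1:2])) + 1e-6)
  # a lower bound is honored for coincident points
  co <- point_pattern(c(0, 0, 1), c(0, 0, 1), c(0, 0, 10, 10))
  expect_equal(loocv_bandwidth(co, sigma_candidates = c(0.5, 5),
                               refine = FALSE)$sigma, 0.5)
})

test_that("the 95% region of one Gaussian is a disk of the analytic area", {
  win <- c(0, 0, 2000, 2000)
  pat <- point_pattern(1000, 1000, win)
  sigma <- 100
  s <- kde_surface(pat, sigma, grid_res = 5)
  hdr <- contour_region(s, 0.95)
  analytic <- pi * (sigma * sqrt(2 * log(20)))^2
  expect_equal(sum(hdr$components$area_m2), analytic, tolerance = 0.05)
  # mass = 1 selects the entire support (every positive-density cell)
  all_cells <- contour_region(s, 1)
  expect_equal(nrow(all_cells$cells), sum(s$z > 0))
  # two well-separated equal kernels give exactly two components
  pat2 <- point_pattern(c(500, 1500), c(500, 1500), win)
  hdr2 <- contour_region(kde_surface(pat2, 60, 10), 0.95)
  expect_equal(nrow(hdr2$components), 2)
})

test_that("the quadrat dispersion statistic matches the closed form", {
  # 2 equal quadrats with counts {4, 0}: X^2 = 4, p = P(chi2_1 > 4)
  pat <- point_pattern(c(100, 200, 300, 400), c(50, 50, 50, 50),
                       c(0, 0, 1000, 100))
  q <- quadrat_test(pat, 500)
  expect_equal(q$statistic, 4)
  expect_equal(q$df, 1)
  expect_equal(q$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(round(q$p_value, 4), 0.0455)
  # perfectly even counts: statistic 0, p 1
  pe <- point_pattern(c(250, 750), c(50, 50), c(0, 0, 1000, 100))
  qe <- quadrat_test(pe, 500)
  expect_equal(qe$statistic, 0)
  expect_equal(qe$p_value, 1)
  # counts partition the pattern, incl. boundary and clipped quadrats
  set.seed(12)
  pat2 <- point_pattern(runif(300, 0, 999), runif(300, 0, 999),
                        c(0, 0, 999, 999))
  q2 <- quadrat_test(pat2, 250)
  expect_equal(sum(q2$quadrats$count), 300)
  # brute-force point-in-rectangle counts agree
  brute <- vapply(seq_len(nrow(q2$quadrats)), function(i) {
    r <- q2$quadrats[i, ]
    xin <- pat2$x >= r$x0 & (pat2$x < r$x1 | (r$x1 == 999 & pat2$x <= r$x1))
    yin <- pat2$y >= r$y0 & (pat2$y < r$y1 | (r$y1 == 999 & pat2$y <= r$y1))
    sum(xin & yin)
  }, 1)
  expect_equal(q2$quadrats$count, brute)
})

test_that("top-risk flagging keeps ties and warns on uniform rates", {
  pat <- point_pattern(runif(50, 0, 1000), runif(50, 0, 1000),
                       c(0, 0, 1000, 1000))
  grid <- quadrat_test(pat, 250)
  fl <- top_risk_areas(grid, 0.05)
  expect_true(all(diff(fl$rate) <= 0))
  expect_true(all(fl$rate >= attr(fl, "cutoff")))
  # uniform rates: everything tied at the cutoff
  uni <- grid
  uni$quadrats$count <- 2
  uni$quadrats$rate <- 2 / uni$quadrats$area_km2
  expect_warning(fl2 <- top_risk_areas(uni, 0.05), "equal")
  expect_equal(nrow(fl2), nrow(uni$quadrats))
})
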