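test_that("population estimation is a weighted sum with complete cells", {
  s <- data.frame(year = 2011, kind = "person", weight = c(2, 3, 5),
                  sex = "M", age_group = "20-24", home_zone = "Z001",
                  origin_zone = NA, dest_zone = NA, is_bicyclist = TRUE)
  pop <- estimate_population(list(s), zone_ids = c("Z001", "Z002"))
  cell <- pop[pop$zone_id == "Z001" & pop$sex == "M" &
              pop$age_group == "20-24", ]
  expect_equal(cell$population, 10)
  # a zone with no bicyclist records is still present, with population 0
  z2 <- pop[pop$zone_id == "Z002", ]
  expect_true(nrow(z2) > 0)
  expect_true(all(z2$population == 0))
  # missing weights are rejected
  s$weight[1] <- NA
  expect_error(estimate_population(list(s)), "weights")
})

test_that("population estimates are invariant to record order and weight splitting", {
  s <- data.frame(year = 2011, kind = "person",
                  weight = c(4, 6, 2), sex = c("M", "F", "M"),
                  age_group = c("20-24", "25-29", "20-24"),
                  home_zone = c("Z001", "Z001", "Z002"),
                  origin_zone = NA, dest_zone = NA, is_bicyclist = TRUE)
  base <- estimate_population(list(s))
  shuffled <- estimate_population(list(s[c(3, 1, 2), ]))
  expect_equal(base, shuffled)
  split <- rbind(s, s)
  split$weight <- split$weight / 2
  expect_equal(estimate_population(list(split))$population, base$population)
})

test_that("shortest paths match a brute-force oracle and break ties lexicographically", {
  city <- small_city()
  cents <- zone_centroids(city$zones)
  ids <- cents$zone_id
  # zero-length path when origin equals destination
  p0 <- shortest_path(city$network, city$zones, ids[1], ids[1])
  expect_equal(p0$length_km, 0)
  # two-node toy network with a single 1 km edge
  toy_net <- structure(list(
    nodes = data.frame(node_id = c("n1", "n2"), x = c(0, 1000), y = c(0, 0)),
    edges = data.frame(edge_id = "e1", node_a = "n1", node_b = "n2",
                       length = 1000)), class = "road_network")
  toy_zones <- structure(list(zones = list(
    list(zone_id = "A", polygon = rect_polygon(c(-10, -10, 500, 10)),
         income_stratum = "low"),
    list(zone_id = "B", polygon = rect_polygon(c(500, -10, 1010, 10)),
         income_stratum = "low")), window = c(-10, -10, 1010, 10)),
    class = "zone_map")
  p <- shortest_path(toy_net, toy_zones, "A", "B")
  expect_equal(p$length_km, 1)
  # distances equal exhaustive Bellman-Ford relaxation on the real lattice
  snap <- stats::setNames(nearest_node(city$network, cents$x, cents$y), ids)
  set.seed(5)
  for (k in 1:6) {
    od <- sample(ids, 2)
    p <- shortest_path(city$network, city$zones, od[1], od[2])
    d_bf <- bf_shortest(city$network$nodes, city$network$edges,
                        snap[[od[1]]], snap[[od[2]]])
    expect_equal(p$length_km * 1000, d_bf, tolerance = 1e-9)
  }
  # determinism incl. the lexicographic tie-break on the lattice
  p1 <- shortest_path(city$network, city$zones, ids[2], ids[9])
  p2 <- shortest_path(city$network, city$zones, ids[2], ids[9])
  expect_identical(p1$nodes, p2$nodes)
})

test_that("kilometer allocation is exact arithmetic and conserves path length", {
  zones <- structure(list(zones = list(
    list(zone_id = "A", polygon = rect_polygon(c(0, -10, 4000, 10)),
         income_stratum = "low"),
    list(zone_id = "B", polygon = rect_polygon(c(4000, -10, 10000, 10)),
         income_stratum = "low")), window = c(0, -10, 10000, 10)),
    class = "zone_map")
  path <- list(coords = matrix(c(0, 0, 10000, 0), 2, 2, byrow = TRUE))
  out <- allocate_vkmt(path, n_trips = 50, zones)
  expect_equal(out$vkmt[out$zone_id == "A"], 200)
  expect_equal(out$vkmt[out$zone_id == "B"], 300)
  expect_equal(sum(out$vkmt), attr(out, "total_km") * 50)
  # a path inside one zone yields a single full-length segment
  inside <- list(coords = matrix(c(100, 0, 3000, 0), 2, 2, byrow = TRUE))
  one <- allocate_vkmt(inside, 10, zones)
  expect_equal(nrow(one), 1)
  expect_equal(one$length_km, 2.9)
})

test_that("kilometer conservation holds over random routed paths", {
  city <- small_city()
  cents <- zone_centroids(city$zones)
  set.seed(31)
  for (k in 1:4) {
    od <- sample(cents$zone_id, 2)
    p <- shortest_path(city$network, city$zones, od[1], od[2])
    if (p$length_km == 0) next
    al <- allocate_vkmt(p, 7, city$zones)
    expect_equal(sum(al$vkmt), p$length_km * 7, tolerance = 1e-9)
  }
})

test_that("stratified interpolation is exact at knots and linear between and beyond", {
  panel <- data.frame(zone_id = "Z001", sex = "M", age_group = "20-24",
                      year = c(2011, 2014, 2015),
                      population = c(100, 140, 150),
                      provenance = "observed")
  out <- interpolate_panel(panel, 2011:2017)
  val <- function(y) out$population[out$year == y]
  expect_equal(val(2013), 100 + 2 * (140 - 100) / 3)
  expect_equal(val(2017), 170)   # forward from the last two observed years
  expect_equal(val(2011), 100)   # exact at knots
  expect_equal(val(2015), 150)
  expect_identical(out$provenance[out$year == 2014], "observed")
  expect_identical(out$provenance[out$year == 2013], "interpolated")
  expect_identical(out$provenance[out$year == 2017], "extrapolated")
  # declining series never extrapolates below zero
  dec <- data.frame(zone_id = "Z001", sex = "M", age_group = "20-24",
                    year = c(2014, 2015), population = c(20, 5),
                    provenance = "observed")
  out2 <- interpolate_panel(dec, 2014:2018)
  expect_true(all(out2$population >= 0))
  expect_error(interpolate_panel(dec[1, ], 2014:2016), "insufficient")
})

test_that("validation errors reproduce the worked percent-error arithmetic", {
  v <- validation_error(1100707, 1063762)
  expect_equal(round(v$total_pct_error, 1), 3.4)
  ident <- validation_error(c(5, 7), c(5, 7))
  expect_equal(ident$total_pct_error, 0)
  expect_equal(ident$mean_stratified_pct_error, 0)
  two <- validation_error(c(100, 100), c(110, 80))
  expect_equal(two$mean_stratified_pct_error, 15)
  expect_error(validation_error(0, 1), "denominator")
  # zero-actual groups are excluded and reported
  z <- validation_error(c(100, 0), c(90, 5))
  expect_equal(z$n_excluded, 1)
})

test_that("estimated zone kilometers track the ground truth", {
  city <- small_city()
  truth <- small_truth()
  surveys <- generate_surveys(city$zones, seed = 3, truth = truth)
  vk <- estimate_vkmt(surveys, city$zones, city$network)
  y <- 2015
  est <- vk[vk$year == y, ]
  tru <- truth$true_vkmt[truth$true_vkmt$year == y, ]
  m <- merge(est, tru, by = "zone_id")
  expect_gt(stats::cor(m$daily_vkmt.x, m$daily_vkmt.y), 0.95)
  expect_lt(abs(sum(m$daily_vkmt.x) - sum(m$daily_vkmt.y)) / sum(m$daily_vkmt.y),
            0.1)
})
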