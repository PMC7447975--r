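# hand-built one-zone fixtures for the standardization arithmetic
flat_exposure <- function(years, pop_per_cell = 1000) {
  cells <- expand.grid(zone_id = "Z001", year = years, sex = c("M", "F"),
                       age_group = age_group_levels(),
                       stringsAsFactors = FALSE)
  cells$population <- pop_per_cell
  cells$provenance <- "observed"
  cells
}

make_events <- function(year, month, n, fatal = 0, sex = "M",
                        age_group = "20-24") {
  if (n == 0) return(NULL)
  data.frame(year = year, month = month, fatal = fatal, sex = sex,
             age_group = age_group, stringsAsFactors = FALSE)[rep(1, n), ]
}

test_that("monthly rates are count over denominator times scale", {
  ex <- flat_exposure(2011)
  # 5 nonfatal events among 20,000 bicyclists in one stratum-uniform city:
  # every stratum rate is 5/pop, so the standardized rate matches 25/1e5
  # when the population is spread as 20,000 over one age-sex cell
  ex$population <- 0
  ex$population[ex$sex == "M" & ex$age_group == "20-24"] <- 20000
  cc <- make_events(2011, 1, 5, sex = "M")
  rates <- monthly_rates(cc, ex, "population")
  r <- rates[rates$month == 1 & rates$outcome == "nonfatal" &
             rates$sex == "all", ]
  expect_equal(r$rate, 25)
  # months with no events have rate zero
  r2 <- rates[rates$month == 2 & rates$outcome == "nonfatal" &
              rates$sex == "all", ]
  expect_equal(r2$rate, 0)
})

test_that("direct standardization returns the common rate under homogeneity", {
  ex <- flat_exposure(2011, pop_per_cell = 500)
  # one event per age group in month 1 (all male): stratum rate 1/500 in
  # every male age stratum
  cc <- do.call(rbind, lapply(age_group_levels(), function(a)
    make_events(2011, 1, 1, sex = "M", age_group = a)))
  rates <- monthly_rates(cc, ex, "population", scale = 1)
  r <- rates[rates$month == 1 & rates$outcome == "nonfatal" & rates$sex == "M", ]
  expect_equal(r$rate, 1 / 500, tolerance = 1e-12)
})

test_that("rates scale inversely with the denominator and ignore row order", {
  ex1 <- flat_exposure(2011, 1000)
  ex2 <- flat_exposure(2011, 3000)
  cc <- rbind(make_events(2011, 3, 4, sex = "F", age_group = "30-34"),
              make_events(2011, 3, 2, sex = "M", age_group = "25-29"))
  r1 <- monthly_rates(cc, ex1, "population")
  r2 <- monthly_rates(cc, ex2, "population")
  expect_equal(r1$rate, r2$rate * 3, tolerance = 1e-12)
  rperm <- monthly_rates(cc[sample(nrow(cc)), ], ex1, "population")
  expect_equal(r1, rperm)
})

test_that("kilometer-based rates use daily kilometers times days in month", {
  vk <- data.frame(zone_id = "Z001", year = 2011, daily_vkmt = 1000,
                   provenance = "observed")
  cc <- make_events(2011, 2, 7)
  rates <- monthly_rates(cc, vk, "vkmt", scale = 1e8)
  r <- rates[rates$month == 2 & rates$outcome == "nonfatal" &
             rates$sex == "all", ]
  expect_equal(r$rate, 7 / (1000 * 28) * 1e8)
})

test_that("yearly summaries average the 12 monthly rates with a t interval", {
  p <- data.frame(month = 1:12, year = 2011, outcome = "fatal", sex = "all",
                  denominator_kind = "population", rate = 10)
  s <- yearly_summary(p)
  expect_equal(s$mean_rate, 10)
  expect_equal(s$ci_hi - s$ci_lo, 0)
  p$rate <- 1:12
  s2 <- yearly_summary(p)
  expect_equal(s2$mean_rate, 6.5)
  half <- stats::qt(0.975, 11) * stats::sd(1:12) / sqrt(12)
  expect_equal(s2$ci_hi, 6.5 + half)
  expect_error(yearly_summary(p[-3, ]), "missing 3")
})

test_that("the t interval covers the true mean about 95% of the time", {
  set.seed(77)
  cover <- 0
  for (r in 1:500) {
    p <- data.frame(month = 1:12, year = 2011, outcome = "fatal", sex = "all",
                    denominator_kind = "population", rate = rnorm(12, 5, 2))
    s <- yearly_summary(p)
    cover <- cover + (s$ci_lo <= 5 && 5 <= s$ci_hi)
  }
  expect_gt(cover / 500, 0.92)
  expect_lt(cover / 500, 0.98)
})

test_that("between-year comparisons return percent change and a p-value", {
  base <- data.frame(month = 1:12, sex = "all", rate = c(10, 12, 9, 11, 10,
    13, 9, 10, 12, 11, 10, 9))
  p <- rbind(transform(base, year = 2011), transform(base, year = 2017))
  same <- compare_years(p, 2011, 2017)
  expect_equal(same$pct_change, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  p2 <- rbind(transform(base, year = 2011),
              transform(base, year = 2017, rate = rate / 2))
  expect_equal(compare_years(p2, 2011, 2017)$pct_change, 50)
  zero <- rbind(transform(base, year = 2011, rate = 0),
                transform(base, year = 2017))
  expect_error(compare_years(zero, 2011, 2017), "undefined change")
})

test_that("sex-difference testing uses the year-by-sex interaction", {
  set.seed(123)
  mk <- function(year, sex, mu) data.frame(month = 1:12, year = year,
                                           sex = sex, rate = rnorm(12, mu, 1))
  p <- rbind(mk(2011, "all", 10), mk(2017, "all", 6),
             mk(2011, "F", 10), mk(2017, "F", 10),   # no change for F
             mk(2011, "M", 10), mk(2017, "M", 4))    # strong drop for M
  r <- compare_years(p, 2011, 2017, by_sex = TRUE)
  expect_lt(r$sex_diff_p, 0.01)
  expect_gt(r$pct_change_m, r$pct_change_f)
})

test_that("standardized mortality ratios follow observed over expected", {
  # direct arithmetic: observed 10, expected 4 gives 2.5
  ex <- flat_exposure(2011, 1000)
  rr <- expand.grid(sex = c("M", "F"), age_group = age_group_levels(),
                    stringsAsFactors = FALSE)
  rr$rate <- 0
  # expected = 4 in every month: put rate on one male stratum
  rr$rate[rr$sex == "M" & rr$age_group == "20-24"] <- 4 / 1000
  cc <- make_events(2011, 1, 10, fatal = 1, sex = "M")
  out <- smr(cc, ex, reference_rates = rr)
  m1 <- out$panel[out$panel$month == 1 & out$panel$sex == "all", ]
  expect_equal(m1$observed, 10)
  expect_equal(m1$expected, 4)
  expect_equal(m1$smr, 2.5)
})

test_that("the study population has overall SMR 1 against its own pooled rates", {
  city <- small_city()
  truth <- small_null_truth()
  cc <- generate_collisions(city$zones, city$network, truth, seed = 6,
                            n_events = 3000)
  pop <- truth$true_population[truth$true_population$year %in% 2011:2017, ]
  out <- smr(cc, pop)
  ov <- out$overall[out$overall$sex == "all", ]
  expect_equal(ov$smr, 1, tolerance = 1e-9)
})

test_that("the standard population weights are normalized", {
  w <- who_standard_population()
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
  expect_true(all(w$weight >= 0))
})
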