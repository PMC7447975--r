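test_that("covariate screening applies the missingness, association and degeneracy rules", {
  set.seed(1)
  n <- 600
  d <- data.frame(fatal = rbinom(n, 1, 0.3))
  d$good <- d$fatal + rnorm(n, 0, 0.8)            # associated
  d$noise <- rnorm(n)                             # independent
  d$holey <- ifelse(runif(n) < 0.15, NA, rnorm(n))  # 15% missing
  d$flat <- 1                                     # constant
  scr <- screen_covariates(d, c("good", "noise", "holey", "flat"))
  expect_true("good" %in% scr$selected)
  lg <- scr$log
  expect_identical(lg$reason[lg$covariate == "holey"], "missingness")
  expect_identical(lg$reason[lg$covariate == "flat"], "degenerate")
  expect_identical(lg$reason[lg$covariate == "noise"], "bivariate p")
  # collinear pair: the one with larger missingness is dropped
  d$good2 <- d$good + rnorm(n, 0, 0.01)
  d$good2[sample(n, 20)] <- NA
  scr2 <- screen_covariates(d, c("good", "good2"))
  expect_identical(scr2$selected, "good")
  expect_identical(scr2$log$reason[scr2$log$covariate == "good2"],
                   "collinearity")
  expect_error(screen_covariates(transform(d, fatal = 0), "good"),
               "zero variance")
})

test_that("oversampling hits the target prevalence exactly on divisible counts", {
  d <- data.frame(fatal = c(rep(0, 700), rep(1, 30)), v = seq_len(730))
  out <- oversample(d, 0.30, seed = 2)
  expect_equal(nrow(out), 1000)
  expect_equal(sum(out$fatal), 300)
  expect_equal(mean(out$fatal), 0.30)
  # negatives untouched
  expect_equal(out$v[out$fatal == 0], d$v[d$fatal == 0])
  # deterministic given the seed
  expect_identical(oversample(d, 0.30, seed = 2), out)
  expect_false(identical(oversample(d, 0.30, seed = 3), out))
  # already at target: unchanged with a warning
  bal <- data.frame(fatal = c(rep(0, 7), rep(1, 3)))
  expect_warning(same <- oversample(bal, 0.30, seed = 1), "already")
  expect_identical(same, bal)
})

test_that("intercept-only fit equals the logit of the observed prevalence", {
  d <- data.frame(fatal = rep(c(1, 0, 0, 0), 50))
  spec <- severity_spec(linear_terms = character(0),
                        smooth_terms = character(0), spatial_smooth = FALSE,
                        random_intercepts = character(0))
  fit <- fit_gamm(d, spec, engine = "gam")
  expect_equal(fit$linear_coefficients$estimate[1], log(1 / 3),
               tolerance = 1e-6)
})

test_that("a single binary covariate matches the closed-form 2x2 log odds ratio", {
  set.seed(33)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-2 + 1.3 * x))
  d <- data.frame(fatal = y, on_bike_path = x)
  spec <- severity_spec(linear_terms = "on_bike_path",
                        smooth_terms = character(0), spatial_smooth = FALSE,
                        random_intercepts = character(0))
  fit <- fit_gamm(d, spec, engine = "gam")
  tab <- table(x, y)
  lor <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  se <- sqrt(sum(1 / tab))
  co <- fit$linear_coefficients
  expect_equal(co$estimate[co$term == "on_bike_path"], lor, tolerance = 1e-6)
  expect_equal(co$se[co$term == "on_bike_path"], se, tolerance = 1e-4)
})

test_that("smooths collapse to the parametric fit as the penalty grows", {
  set.seed(41)
  n <- 2000
  x <- runif(n, 0, 4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  d <- data.frame(fatal = y, x = x)
  heavy <- mgcv::gam(fatal ~ s(x, bs = "tp", k = 10), family = binomial(),
                     data = d, sp = 1e8)
  straight <- glm(fatal ~ x, family = binomial(), data = d)
  expect_equal(as.numeric(predict(heavy, newdata = data.frame(x = c(1, 2, 3)))),
               as.numeric(predict(straight, newdata = data.frame(x = c(1, 2, 3)))),
               tolerance = 1e-3)
})

test_that("oversampling changes the intercept but not the slopes in expectation", {
  set.seed(52)
  hit <- 0
  for (r in 1:10) {
    n <- 4000
    x <- rbinom(n, 1, 0.5)
    d <- data.frame(fatal = rbinom(n, 1, plogis(-3 + 1.2 * x)),
                    on_bike_path = x)
    spec <- severity_spec(linear_terms = "on_bike_path",
                          smooth_terms = character(0), spatial_smooth = FALSE,
                          random_intercepts = character(0))
    raw <- fit_gamm(d, spec, engine = "gam")$linear_coefficients
    bal <- fit_gamm(oversample(d, 0.30, seed = r), spec,
                    engine = "gam")$linear_coefficients
    b_raw <- raw[raw$term == "on_bike_path", ]
    b_bal <- bal[bal$term == "on_bike_path", ]
    hit <- hit + (abs(b_bal$estimate - b_raw$estimate) <=
                    2 * sqrt(b_raw$se^2 + b_bal$se^2))
  }
  expect_gte(hit, 8)
})

test_that("smooth thresholds interpolate the confidence-band zero crossings", {
  # synthetic fit object: band significant for x >= 5 exactly
  x <- seq(0, 10, length.out = 101)
  fitv <- x - 5
  sm <- data.frame(x = x, fit = fitv, se = 0.5,
                   lo = fitv - 1, hi = fitv + 1)
  obj <- structure(list(smooths = list(slope_pct = sm)),
                   class = "severity_fit")
  th <- smooth_thresholds(obj, "slope_pct")
  # hi crosses 0 at x = 4 (end of the negative-significant region) and lo
  # crosses 0 at x = 6 (start of the positive-significant region)
  expect_equal(as.numeric(th), c(4, 6), tolerance = 1e-9)
  # a band entirely above zero is one full-range interval, no crossings
  sm2 <- transform(sm, fit = 2, lo = 1, hi = 3)
  obj2 <- structure(list(smooths = list(slope_pct = sm2)),
                    class = "severity_fit")
  th2 <- smooth_thresholds(obj2, "slope_pct")
  expect_length(as.numeric(th2), 0)
  iv <- attr(th2, "intervals")
  expect_equal(c(iv$from, iv$to), c(0, 10))
  # a never-significant band yields an empty list
  sm3 <- transform(sm, fit = 0, lo = -1, hi = 1)
  obj3 <- structure(list(smooths = list(slope_pct = sm3)),
                    class = "severity_fit")
  expect_length(as.numeric(smooth_thresholds(obj3, "slope_pct")), 0)
  expect_error(smooth_thresholds(obj3, "nope"), "not fitted")
})

test_that("a null smooth is declared not significant almost always", {
  set.seed(61)
  empty <- 0
  spec <- severity_spec(linear_terms = character(0), smooth_terms = "slope_pct",
                        spatial_smooth = FALSE,
                        random_intercepts = character(0))
  for (r in 1:10) {
    d <- data.frame(fatal = rbinom(3000, 1, 0.1),
                    slope_pct = rgamma(3000, 2, 1))
    fit <- fit_gamm(d, spec, engine = "gam")
    empty <- empty + (length(as.numeric(smooth_thresholds(fit, "slope_pct"))) == 0)
  }
  expect_gte(empty, 9)
})

test_that("traffic-stress ratings follow the ordered rule table", {
  seg <- data.frame(
    lanes = c(2, 4, 2, 3),
    lane_width = c(3.5, 3.0, 3.2, 3.4),
    speed_limit = c(60, 80, 30, 50),
    has_bike_path = c(1, 0, 0, 0),
    has_transit_route = c(0, 1, 0, 1))
  r <- lts_rating(seg)
  expect_equal(r$rating, c(1L, 4L, 2L, 3L))
  expect_equal(r$lts4, c(0L, 1L, 0L, 0L))
  expect_identical(lts_rating(seg), lts_rating(seg))
  expect_error(lts_rating(seg[, -1]), "missing attribute")
})

test_that("stratified fits skip single-class strata and recover sex-specific effects", {
  set.seed(71)
  # females only: strong bike-path effect; males: none
  mk <- function(sex, n, beta) data.frame(
    sex = sex, on_bike_path = rbinom(n, 1, 0.5)) -> d0
  nf <- 3000; nm <- 3000
  xf <- rbinom(nf, 1, 0.5); xm <- rbinom(nm, 1, 0.5)
  d <- rbind(
    data.frame(sex = "F", on_bike_path = xf,
               fatal = rbinom(nf, 1, plogis(-2.5 + 1.5 * xf))),
    data.frame(sex = "M", on_bike_path = xm,
               fatal = rbinom(nm, 1, plogis(-2.5))))
  spec <- severity_spec(linear_terms = c("sex", "on_bike_path"),
                        smooth_terms = character(0), spatial_smooth = FALSE,
                        random_intercepts = character(0))
  out <- stratified_fit(d, spec, strata = "sex", engine = "gam")
  cf <- out$strata$F$linear_coefficients
  cm <- out$strata$M$linear_coefficients
  bf <- cf[cf$term == "on_bike_path", ]
  bm <- cm[cm$term == "on_bike_path", ]
  expect_lt(bf$p, 0.05)
  expect_gt(bm$p, 0.05)
  # a stratum with no fatal events is skipped with a diagnostic
  d2 <- d
  d2$fatal[d2$sex == "M"] <- 0
  out2 <- stratified_fit(d2, spec, strata = "sex", engine = "gam")
  expect_null(out2$strata$M)
  expect_identical(out2$skipped$M, "single outcome class")
})
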