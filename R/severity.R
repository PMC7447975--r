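# Fatality-risk modelling: a binomial generalized additive mixed model
# with penalized thin-plate smooths, a 2-D spatial smooth and nested
# random intercepts (fitted by restricted-likelihood criteria through
# mgcv), plus covariate screening, minority-class oversampling,
# smooth-threshold extraction and traffic-stress ratings.

#' Model specification for the fatality-risk GAMM
#'
#' @param linear_terms categorical/binary covariates entering unpenalized
#'   (reference levels: vehicle_type = automobile, weekday = Sunday).
#' @param smooth_terms continuous covariates entering as penalized
#'   thin-plate splines (rank `k_smooth`); `time_of_day` is treated as a
#'   cyclic smooth over 24 h.
#' @param spatial_smooth include a 2-D penalized smooth of the event
#'   coordinates (rank `k_spatial`).
#' @param random_intercepts grouping columns for Gaussian random
#'   intercepts; `"zone_year"` adds year nested within zone.
#' @param k_smooth,k_spatial basis dimensions.
#' @return a `severity_spec` list.
#' @export
severity_spec <- function(linear_terms = c("sex", "vehicle_type", "weekday",
                                           "on_bike_path", "transit_presence",
                                           "lts4"),
                          smooth_terms = c("slope_pct", "surface_failures",
                                           "time_of_day", "age"),
                          spatial_smooth = TRUE,
                          random_intercepts = c("zone_id", "zone_year"),
                          k_smooth = 10, k_spatial = 30) {
  both <- intersect(linear_terms, smooth_terms)
  if (length(both))
    stop("covariates in both linear and smooth lists: ",
         paste(both, collapse = ", "))
  structure(list(linear_terms = linear_terms, smooth_terms = smooth_terms,
                 spatial_smooth = spatial_smooth,
                 random_intercepts = random_intercepts,
                 k_smooth = k_smooth, k_spatial = k_spatial),
            class = "severity_spec")
}

#' Screen candidate covariates
#'
#' Keeps covariates whose bivariate association with the fatality outcome
#' has p < `p_cut` (chi-square for categorical, Wilcoxon rank-sum for
#' continuous), whose missingness is below `miss_cut`, and which are not
#' collinear (pairwise |r| >= `r_cut` drops the covariate with the larger
#' missingness). Degenerate (constant) covariates are dropped.
#'
#' @param data collision table with a binary `fatal` outcome.
#' @param candidates covariate names to screen.
#' @param p_cut bivariate p-value threshold (default 0.2).
#' @param miss_cut missingness threshold (default 0.10).
#' @param r_cut collinearity threshold on |Pearson r| (default 0.8).
#' @return list: `selected` (names), `log` (covariate, decision, reason,
#'   p_value, missingness).
#' @export
screen_covariates <- function(data, candidates, p_cut = 0.2,
                              miss_cut = 0.10, r_cut = 0.8) {
  y <- data$fatal
  if (length(unique(stats::na.omit(y))) < 2)
    stop("invalid data: outcome has zero variance")
  log <- data.frame(covariate = character(0), decision = character(0),
                    reason = character(0), p_value = numeric(0),
                    missingness = numeric(0), stringsAsFactors = FALSE)
  add <- function(cv, dec, rea, p, miss)
    rbind(log, data.frame(covariate = cv, decision = dec, reason = rea,
                          p_value = p, missingness = miss,
                          stringsAsFactors = FALSE))
  kept <- character(0)
  for (cv in candidates) {
    x <- data[[cv]]
    miss <- mean(is.na(x))
    if (miss >= miss_cut) { log <- add(cv, "excluded", "missingness", NA, miss); next }
    xs <- x[!is.na(x)]
    if (length(unique(xs)) < 2) { log <- add(cv, "excluded", "degenerate", NA, miss); next }
    ok <- !is.na(x)
    p <- if (is.numeric(x) && length(unique(xs)) > 5) {
      stats::wilcox.test(x[ok] ~ y[ok])$p.value
    } else {
      suppressWarnings(stats::chisq.test(table(x[ok], y[ok]))$p.value)
    }
    if (!is.finite(p) || p >= p_cut) {
      log <- add(cv, "excluded", "bivariate p", p, miss)
    } else {
      kept <- c(kept, cv)
      log <- add(cv, "kept", "", p, miss)
    }
  }
  num <- kept[vapply(kept, function(cv) is.numeric(data[[cv]]), TRUE)]
  if (length(num) > 1) {
    cm <- suppressWarnings(stats::cor(data[num], use = "pairwise.complete.obs"))
    drop <- character(0)
    for (i in seq_along(num)) for (j in seq_len(i - 1)) {
      if (num[i] %in% drop || num[j] %in% drop) next
      if (is.finite(cm[i, j]) && abs(cm[i, j]) >= r_cut) {
        mi <- mean(is.na(data[[num[i]]])); mj <- mean(is.na(data[[num[j]]]))
        loser <- if (mi >= mj) num[i] else num[j]
        drop <- c(drop, loser)
        log$decision[log$covariate == loser] <- "excluded"
        log$reason[log$covariate == loser] <- "collinearity"
      }
    }
    kept <- setdiff(kept, drop)
  }
  list(selected = kept, log = log)
}

#' Oversample the minority (fatal) class to a target prevalence
#'
#' Appends fatal rows resampled with replacement until the positive
#' fraction first reaches the target; negatives are untouched. On counts
#' where the target is exactly attainable the final fraction is exact.
#'
#' @param data collision table with binary `fatal`.
#' @param target_positive_fraction target prevalence (default 0.30).
#' @param seed integer seed (resampling is deterministic given it).
#' @return the balanced table; attribute "oversample_index" holds the
#'   source row indices of the appended rows.
#' @export
oversample <- function(data, target_positive_fraction = 0.30, seed = 1L) {
  t <- target_positive_fraction
  pos <- which(data$fatal == 1); neg <- which(data$fatal == 0)
  cur <- length(pos) / nrow(data)
  if (cur >= t) {
    warning("positive fraction already at or above target; returning data unchanged")
    return(data)
  }
  m <- ceiling(t * length(neg) / (1 - t))   # total positives needed
  extra <- with_seed(seed, sample(pos, m - length(pos), replace = TRUE))
  out <- rbind(data, data[extra, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "oversample_index") <- extra
  out
}

# Coerce modelling columns: declared factor baselines and grouping factors.
prepare_model_frame <- function(data, spec) {
  df <- data
  if ("vehicle_type" %in% names(df))
    df$vehicle_type <- stats::relevel(factor(df$vehicle_type), "automobile")
  if ("weekday" %in% names(df))
    df$weekday <- factor(df$weekday,
                         levels = c("Sunday", "Monday", "Tuesday", "Wednesday",
                                    "Thursday", "Friday", "Saturday"))
  if ("sex" %in% names(df)) {
    df$sex <- factor(df$sex)
    if ("F" %in% levels(df$sex))
      df$sex <- stats::relevel(df$sex, "F")
  }
  if ("zone_id" %in% names(df)) df$zone_f <- factor(df$zone_id)
  if (all(c("zone_id", "year") %in% names(df)))
    df$zone_year_f <- factor(paste(df$zone_id, df$year, sep = ":"))
  df
}

build_gamm_formula <- function(spec, data) {
  rhs <- character(0)
  lin <- intersect(spec$linear_terms, names(data))
  lin <- lin[vapply(lin, function(v)
    length(unique(stats::na.omit(data[[v]]))) > 1, TRUE)]
  rhs <- c(rhs, lin)
  for (sm in intersect(spec$smooth_terms, names(data))) {
    if (length(unique(stats::na.omit(data[[sm]]))) < spec$k_smooth) next
    rhs <- c(rhs, if (sm == "time_of_day")
      sprintf("s(time_of_day, bs = 'cc', k = %d)", spec$k_smooth)
      else sprintf("s(%s, bs = 'tp', k = %d)", sm, spec$k_smooth))
  }
  if (isTRUE(spec$spatial_smooth) && all(c("x", "y") %in% names(data)))
    rhs <- c(rhs, sprintf("s(x, y, bs = 'tp', k = %d)", spec$k_spatial))
  if ("zone_id" %in% spec$random_intercepts && "zone_f" %in% names(data) &&
      nlevels(data$zone_f) > 1)
    rhs <- c(rhs, "s(zone_f, bs = 're')")
  if ("zone_year" %in% spec$random_intercepts && "zone_year_f" %in% names(data) &&
      nlevels(data$zone_year_f) > 1)
    rhs <- c(rhs, "s(zone_year_f, bs = 're')")
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste("fatal ~", paste(rhs, collapse = " + ")))
}

#' Fit the binomial fatality-risk GAMM
#'
#' Penalized-likelihood binomial fit with logit link: unpenalized linear
#' terms, low-rank thin-plate splines for continuous covariates (cyclic
#' for time of day), an optional 2-D spatial smooth of the event
#' coordinates, and Gaussian random intercepts for zone and year-in-zone.
#' Smoothing and variance parameters are chosen by a restricted-likelihood
#' criterion (fast REML for large samples, REML otherwise) via mgcv.
#'
#' @param data collision table (screened covariates only).
#' @param spec a [severity_spec()].
#' @param engine "auto" (bam + fREML when n >= 4000, else gam + REML),
#'   "gam" or "bam".
#' @return a `severity_fit` list: `model` (the mgcv fit),
#'   `linear_coefficients` (term, estimate, se, p, stars, separation),
#'   `smooths` (per term: grid x, fit, se, lo, hi), `random_sd`, `n_obs`,
#'   `converged`, `formula`.
#' @export
fit_gamm <- function(data, spec = severity_spec(), engine = "auto") {
  df <- prepare_model_frame(data, spec)
  form <- build_gamm_formula(spec, df)
  n <- nrow(df)
  knots <- if (grepl("time_of_day", deparse1(form)))
    list(time_of_day = c(0, 24)) else NULL
  use_bam <- engine == "bam" || (engine == "auto" && n >= 4000)
  fit <- if (use_bam)
    mgcv::bam(form, family = stats::binomial(), data = df, knots = knots,
              method = "fREML", discrete = TRUE)
  else
    mgcv::gam(form, family = stats::binomial(), data = df, knots = knots,
              method = "REML")
  sm <- summary(fit)
  pt <- sm$p.table
  stars <- cut(pt[, 4], c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
               labels = c("***", "**", "*", ".", ""))
  lin <- data.frame(term = rownames(pt), estimate = pt[, 1], se = pt[, 2],
                    p = pt[, 4], stars = as.character(stars),
                    separation = abs(pt[, 1]) > 8 & pt[, 2] > 50,
                    stringsAsFactors = FALSE, row.names = NULL)

  smooths <- list()
  for (lbl in vapply(fit$smooth, function(s) s$label, character(1))) {
    s_obj <- fit$smooth[[which(vapply(fit$smooth, function(s) s$label,
                                      character(1)) == lbl)]]
    if (length(s_obj$term) != 1 || !is.null(s_obj$xt$is_re) ||
        inherits(s_obj, "random.effect")) next
    v <- s_obj$term
    if (!is.numeric(df[[v]])) next
    xr <- range(df[[v]], na.rm = TRUE)
    grid <- df[rep(1L, 100), , drop = FALSE]
    grid[[v]] <- seq(xr[1], xr[2], length.out = 100)
    pr <- if (use_bam)
      stats::predict(fit, newdata = grid, type = "terms", terms = lbl,
                     se.fit = TRUE, discrete = FALSE)
    else
      stats::predict(fit, newdata = grid, type = "terms", terms = lbl,
                     se.fit = TRUE)
    smooths[[v]] <- data.frame(
      x = grid[[v]], fit = as.numeric(pr$fit),
      se = as.numeric(pr$se.fit),
      lo = as.numeric(pr$fit) - 1.96 * as.numeric(pr$se.fit),
      hi = as.numeric(pr$fit) + 1.96 * as.numeric(pr$se.fit))
  }

  random_sd <- tryCatch({
    utils::capture.output(vc <- mgcv::gam.vcomp(fit))
    if (is.matrix(vc)) stats::setNames(vc[, 1], rownames(vc)) else vc
  }, error = function(e) NULL)

  structure(list(model = fit, linear_coefficients = lin, smooths = smooths,
                 random_sd = random_sd, n_obs = n,
                 converged = isTRUE(fit$converged) || is.null(fit$converged),
                 formula = form),
            class = "severity_fit")
}

#' Significance thresholds of a fitted smooth
#'
#' Finds the covariate values where the 95% confidence band of the smooth's
#' log-odds contribution crosses zero (equivalently, where the odds-ratio
#' band leaves or enters 1), by linear interpolation on the evaluation
#' grid.
#'
#' @param fit a `severity_fit`.
#' @param term smooth term name.
#' @return numeric vector of crossing points (empty when the band never
#'   excludes zero); attribute "intervals" holds the significant ranges.
#' @export
smooth_thresholds <- function(fit, term) {
  sm <- fit$smooths[[term]]
  if (is.null(sm)) stop("term not fitted with a CI band: ", term)
  sig <- (sm$lo > 0) | (sm$hi < 0)
  th <- numeric(0)
  iv <- list()
  if (!any(sig)) {
    out <- th
    attr(out, "intervals") <- data.frame(from = numeric(0), to = numeric(0))
    return(out)
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    a <- starts[k]; b <- ends[k]
    from <- if (a == 1) sm$x[1] else {
      # interpolate the band edge that changes sign between a-1 and a
      edge <- if (sm$lo[a] > 0) sm$lo else sm$hi
      cross_zero(sm$x[a - 1], sm$x[a], edge[a - 1], edge[a])
    }
    to <- if (b == nrow(sm)) sm$x[nrow(sm)] else {
      edge <- if (sm$lo[b] > 0) sm$lo else sm$hi
      cross_zero(sm$x[b], sm$x[b + 1], edge[b], edge[b + 1])
    }
    if (a > 1) th <- c(th, from)
    if (b < nrow(sm)) th <- c(th, to)
    iv[[length(iv) + 1L]] <- c(from, to)
  }
  out <- th
  attr(out, "intervals") <- do.call(rbind, lapply(iv, function(v)
    data.frame(from = v[1], to = v[2])))
  out
}

cross_zero <- function(x0, x1, y0, y1) {
  if (y1 == y0) return((x0 + x1) / 2)
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' Default traffic-stress rule table
#'
#' Ordered first-match rules assigning a Level of Traffic Stress rating
#' 1-4 from segment attributes, following the usual LTS criteria: a
#' dedicated bike path gives LTS 1; few lanes and low speed give LTS 2;
#' moderate roads give LTS 3; wide or fast roads give LTS 4. The final
#' catch-all makes the table total. NA means "any value".
#'
#' @return data.frame of rules (max_lanes, max_speed, needs_bike_path,
#'   rating), matched in row order.
#' @export
default_lts_rules <- function() {
  data.frame(
    max_lanes  = c(NA, 2, 3, NA),
    max_speed  = c(NA, 40, 50, NA),
    needs_bike_path = c(1, NA, NA, NA),
    rating = c(1L, 2L, 3L, 4L))
}

#' Level-of-Traffic-Stress rating for road segments
#'
#' First-matching-rule lookup over the rule table; also returns the high
#' stress flag `lts4 = (rating == 4)`.
#'
#' @param segments data.frame with lanes, lane_width, speed_limit,
#'   has_bike_path, has_transit_route.
#' @param rules rule table (default [default_lts_rules()]).
#' @return data.frame: rating (1-4), lts4 (0/1).
#' @export
lts_rating <- function(segments, rules = default_lts_rules()) {
  need <- c("lanes", "speed_limit", "has_bike_path")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("missing attribute(s): ", paste(miss, collapse = ", "))
  n <- nrow(segments)
  rating <- rep(NA_integer_, n)
  for (r in seq_len(nrow(rules))) {
    ok <- rep(TRUE, n)
    if (!is.na(rules$max_lanes[r])) ok <- ok & segments$lanes <= rules$max_lanes[r]
    if (!is.na(rules$max_speed[r])) ok <- ok & segments$speed_limit <= rules$max_speed[r]
    if (!is.na(rules$needs_bike_path[r]))
      ok <- ok & segments$has_bike_path == rules$needs_bike_path[r]
    fill <- is.na(rating) & ok
    rating[fill] <- rules$rating[r]
  }
  if (any(is.na(rating))) stop("rule table is not total")
  data.frame(rating = rating, lts4 = as.integer(rating == 4L))
}

#' Sex-stratified and pooled fatality-risk fits
#'
#' Fits the same specification independently within each stratum and on
#' the pooled data; strata with a single outcome class are skipped with a
#' diagnostic.
#'
#' @param data collision table.
#' @param spec a [severity_spec()] (the stratifying variable is removed
#'   from the linear terms for the stratum fits).
#' @param strata stratifying column (default "sex").
#' @param engine passed to [fit_gamm()].
#' @return list: `strata` (named list of `severity_fit` or NULL),
#'   `pooled`, `skipped` (named reasons).
#' @export
stratified_fit <- function(data, spec = severity_spec(), strata = "sex",
                           engine = "auto") {
  levels <- sort(unique(data[[strata]]))
  spec_s <- spec
  spec_s$linear_terms <- setdiff(spec$linear_terms, strata)
  fits <- list(); skipped <- list()
  for (lv in levels) {
    d <- data[data[[strata]] == lv, , drop = FALSE]
    if (length(unique(d$fatal)) < 2) {
      skipped[[as.character(lv)]] <- "single outcome class"
      next
    }
    fits[[as.character(lv)]] <- fit_gamm(d, spec_s, engine)
  }
  list(strata = fits, pooled = fit_gamm(data, spec, engine),
       skipped = skipped)
}
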