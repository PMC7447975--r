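# Standardized collision-rate trends: direct standardization of monthly
# fatal/nonfatal rates by bicyclist population (age-standardized) and by
# bicycle kilometers traveled, yearly summaries with t-based confidence
# intervals, between-year and between-sex comparisons, and indirect
# standardization (standardized mortality ratios).

#' WHO World Standard Population weights
#'
#' The 2000-2025 world standard population by quinquennial age group
#' (Ahmad et al. 2001 table), renormalized to sum exactly to 1.
#'
#' @return data.frame with `age_group` and `weight`; attribute "source".
#' @export
who_standard_population <- function() {
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  labs <- c("00-04", age_group_levels())
  out <- data.frame(age_group = labs, weight = w / sum(w),
                    stringsAsFactors = FALSE)
  attr(out, "source") <- "WHO World Standard Population 2000-2025"
  out
}

days_in_month <- function(year, month) {
  d <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
  d + ifelse(month == 2 & (year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0)),
             1L, 0L)
}

# Direct standardization of one month: counts and person (or km) totals per
# age group, weighted by the standard. Weights are renormalized over age
# groups with positive denominator so that a common stratum rate passes
# through unchanged; an age group with events but zero denominator makes
# the cell undefined (NA).
direct_rate <- function(counts, denom, weights, scale) {
  stopifnot(length(counts) == length(denom), length(denom) == length(weights))
  if (any(counts > 0 & denom <= 0)) return(NA_real_)
  use <- denom > 0
  if (!any(use)) return(if (sum(counts) == 0) 0 else NA_real_)
  w <- weights[use] / sum(weights[use])
  sum(w * counts[use] / denom[use]) * scale
}

#' Monthly standardized collision rates
#'
#' Computes, for every month of the analysis period, outcome (fatal,
#' nonfatal) and sex (F, M, all), the directly standardized rate: by
#' bicyclist population (age-standardized to `standard`, events per
#' `scale` persons) or by kilometers traveled (events per `scale` km,
#' using daily kilometers times days in month).
#'
#' @param collisions collision table (needs year, month, fatal, sex,
#'   age_group).
#' @param exposure exposure panel covering all collision years: population
#'   panel (zone_id, year, sex, age_group, population) for
#'   `denominator_kind = "population"`, or a vkmt panel (zone_id, year,
#'   daily_vkmt) for `"vkmt"`.
#' @param denominator_kind "population" or "vkmt".
#' @param scale events per how many denominator units (default 1e5 persons,
#'   1e8 km).
#' @param standard standard population table ([who_standard_population()]).
#' @return rate panel data.frame: month, year, outcome, sex,
#'   denominator_kind, rate (NA where a nonzero count met a zero
#'   denominator).
#' @export
monthly_rates <- function(collisions, exposure,
                          denominator_kind = c("population", "vkmt"),
                          scale = NULL,
                          standard = who_standard_population()) {
  denominator_kind <- match.arg(denominator_kind)
  scale <- scale %||% if (denominator_kind == "population") 1e5 else 1e8
  years <- sort(unique(collisions$year))
  if (!all(years %in% exposure$year))
    stop("exposure panel does not cover all collision years")
  sexes <- c("F", "M", "all")
  ages <- age_group_levels()
  out <- list()
  for (y in years) {
    ex <- exposure[exposure$year == y, ]
    for (m in 1:12) {
      cc <- collisions[collisions$year == y & collisions$month == m, ]
      for (oc in c("fatal", "nonfatal")) {
        ev <- if (oc == "fatal") cc[cc$fatal == 1, ] else cc[cc$fatal == 0, ]
        for (sx in sexes) {
          evs <- if (sx == "all") ev else ev[ev$sex == sx, ]
          if (denominator_kind == "population") {
            exs <- if (sx == "all") ex else ex[ex$sex == sx, ]
            denom <- vapply(ages, function(a)
              sum(exs$population[exs$age_group == a]), 1)
            counts <- vapply(ages, function(a)
              sum(evs$age_group == a, na.rm = TRUE), 1)
            w <- standard$weight[match(ages, standard$age_group)]
            rate <- direct_rate(counts, denom, w, scale)
          } else {
            km <- sum(ex$daily_vkmt) * days_in_month(y, m)
            # kilometers are not sex-attributed; apportion by event share
            rate <- if (km > 0) nrow(evs) / km * scale
                    else if (nrow(evs) == 0) 0 else NA_real_
          }
          out[[length(out) + 1L]] <- data.frame(
            month = m, year = y, outcome = oc, sex = sx,
            denominator_kind = denominator_kind, rate = rate,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Yearly means of monthly rates with 95% confidence intervals
#'
#' For each year (and outcome/sex/denominator combination present), the
#' mean of the 12 monthly rates with a t-based 95% CI (df = months - 1).
#' Months with undefined rates (zero denominator, nonzero count) are
#' excluded from the mean and counted in `n_excluded`.
#'
#' @param panel a rate panel from [monthly_rates()] (or any data frame with
#'   month, year, rate and optional grouping columns).
#' @return data.frame: grouping columns, year, mean_rate, ci_lo, ci_hi,
#'   n_months, n_excluded.
#' @export
yearly_summary <- function(panel) {
  gcols <- intersect(c("outcome", "sex", "denominator_kind"), names(panel))
  key <- do.call(paste, c(panel[c(gcols, "year")], sep = "\r"))
  out <- lapply(unique(key), function(k) {
    rows <- panel[key == k, ]
    miss <- setdiff(1:12, rows$month)
    if (length(miss))
      stop("insufficient months for ", gsub("\r", "/", k),
           ": missing ", paste(miss, collapse = ", "))
    r <- rows$rate[!is.na(rows$rate)]
    n <- length(r)
    m <- mean(r)
    half <- if (n >= 2 && stats::sd(r) > 0)
      stats::qt(0.975, n - 1) * stats::sd(r) / sqrt(n) else 0
    cbind(rows[1, c(gcols, "year"), drop = FALSE],
          data.frame(mean_rate = m, ci_lo = m - half, ci_hi = m + half,
                     n_months = n, n_excluded = 12 - n))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare two years of monthly rates
#'
#' Percent change `100 * (mean_a - mean_b) / mean_a` between the two sets
#' of 12 monthly rates, with a Welch two-sample t test. With
#' `by_sex = TRUE`, also tests whether the change differs between sexes
#' via the year-by-sex interaction of a linear model on the monthly rates.
#'
#' @param panel a rate panel (single outcome/denominator combination).
#' @param year_a,year_b years to compare (a is the baseline).
#' @param by_sex test the sex difference of the change.
#' @return list: pct_change, p_value, and with `by_sex` also
#'   pct_change_f, pct_change_m, sex_diff_p.
#' @export
compare_years <- function(panel, year_a, year_b, by_sex = FALSE) {
  pick <- function(y, sx) {
    r <- panel$rate[panel$year == y & panel$sex == sx]
    r[!is.na(r)]
  }
  ra <- pick(year_a, "all"); rb <- pick(year_b, "all")
  if (length(ra) < 2 || length(rb) < 2)
    stop("both years must have summarized monthly rates")
  if (mean(ra) == 0) stop("undefined change: baseline mean rate is zero")
  res <- list(
    pct_change = 100 * (mean(ra) - mean(rb)) / mean(ra),
    p_value = stats::t.test(ra, rb)$p.value)
  if (by_sex) {
    dat <- do.call(rbind, lapply(c(year_a, year_b), function(y)
      do.call(rbind, lapply(c("F", "M"), function(sx) {
        r <- pick(y, sx)
        if (length(r) == 0) return(NULL)
        data.frame(rate = r, year = factor(y, levels = c(year_a, year_b)),
                   sex = sx)
      }))))
    fit <- stats::lm(rate ~ year * sex, data = dat)
    ct <- summary(fit)$coefficients
    irow <- grep(":", rownames(ct))
    res$sex_diff_p <- if (length(irow)) ct[irow[1], 4] else NA_real_
    fa <- pick(year_a, "F"); fb <- pick(year_b, "F")
    ma <- pick(year_a, "M"); mb <- pick(year_b, "M")
    res$pct_change_f <- if (mean(fa) > 0) 100 * (mean(fa) - mean(fb)) / mean(fa) else NA
    res$pct_change_m <- if (mean(ma) > 0) 100 * (mean(ma) - mean(mb)) / mean(ma) else NA
  }
  res
}

#' Standardized mortality ratios by indirect standardization
#'
#' For each month, observed fatal events divided by the expected count
#' obtained by applying reference age-specific monthly death rates to the
#' study population. Reference rates default to the internal all-years
#' pooled study rates (per person-month, by sex and age group), so the
#' study population's overall SMR against itself is exactly 1.
#'
#' @param collisions collision table.
#' @param exposure population exposure panel covering the collision years.
#' @param standard standard population (carried for age alignment;
#'   indirect standardization does not weight by it).
#' @param reference_rates optional data.frame (sex, age_group, rate =
#'   deaths per person-month); defaults to pooled internal rates.
#' @return list: `panel` (month, year, sex, observed, expected, smr),
#'   `yearly` (year, sex, mean SMR, 95% CI), `overall` (sex, observed,
#'   expected, smr), `reference_rates`.
#' @export
smr <- function(collisions, exposure, standard = who_standard_population(),
                reference_rates = NULL) {
  ages <- age_group_levels()
  if (!all(stats::na.omit(unique(collisions$age_group)) %in% ages) ||
      !all(unique(exposure$age_group) %in% ages))
    stop("schema error: misaligned age groups")
  years <- sort(unique(collisions$year))
  fatal <- collisions[collisions$fatal == 1, ]

  if (is.null(reference_rates)) {
    person_months <- stats::aggregate(
      population ~ sex + age_group, data = exposure[exposure$year %in% years, ],
      FUN = sum)
    person_months$population <- person_months$population * 12
    deaths <- stats::aggregate(fatal ~ sex + age_group, data = fatal, FUN = length)
    names(deaths)[3] <- "n"
    rr <- merge(person_months, deaths, by = c("sex", "age_group"), all.x = TRUE)
    rr$n[is.na(rr$n)] <- 0
    rr$rate <- ifelse(rr$population > 0, rr$n / rr$population, 0)
    reference_rates <- rr[, c("sex", "age_group", "rate")]
  }

  rows <- list()
  for (y in years) {
    ex <- exposure[exposure$year == y, ]
    for (m in 1:12) {
      fm <- fatal[fatal$year == y & fatal$month == m, ]
      for (sx in c("F", "M", "all")) {
        exs <- if (sx == "all") ex else ex[ex$sex == sx, ]
        rrs <- if (sx == "all") reference_rates else
          reference_rates[reference_rates$sex == sx, ]
        obs <- if (sx == "all") nrow(fm) else sum(fm$sex == sx)
        expd <- 0
        for (sx2 in unique(exs$sex)) {
          pop <- vapply(ages, function(a)
            sum(exs$population[exs$sex == sx2 & exs$age_group == a]), 1)
          rt <- reference_rates$rate[
            match(paste(sx2, ages),
                  paste(reference_rates$sex, reference_rates$age_group))]
          rt[is.na(rt)] <- 0
          expd <- expd + sum(rt * pop)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          month = m, year = y, sex = sx, observed = obs, expected = expd,
          smr = if (expd > 0) obs / expd else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  panel <- do.call(rbind, rows)
  yearly <- yearly_summary(transform(panel, rate = smr))
  names(yearly)[names(yearly) == "mean_rate"] <- "mean_smr"
  overall <- stats::aggregate(cbind(observed, expected) ~ sex, data = panel,
                              FUN = sum)
  overall$smr <- overall$observed / overall$expected
  list(panel = panel, yearly = yearly, overall = overall,
       reference_rates = reference_rates)
}

#' Percent change between two values
#'
#' `100 * (a - b) / a`: the percent reduction from `a` to `b` when b < a.
#'
#' @param a baseline value (nonzero).
#' @param b comparison value.
#' @return percent change.
#' @export
percent_change <- function(a, b) {
  if (a == 0) stop("undefined change: baseline is zero")
  100 * (a - b) / a
}
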