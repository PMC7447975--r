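#!/usr/bin/env Rscript
# Stage 3 — standardized collision-rate trends.
#
# Monthly fatal/nonfatal rates directly standardized by bicyclist
# population (per 100,000, age-standardized to the WHO world standard)
# and by kilometers traveled (per 100 million km), yearly means with 95%
# t-intervals, 2011-vs-2017 comparisons by sex, and monthly standardized
# mortality ratios against the pooled internal reference.

library(cyclesafe)

out <- "results/synthetic"
collisions <- read_collisions(file.path(out, "collisions.csv"))
pop <- read_exposure(file.path(out, "exposure_population.csv"))
vk <- read_exposure(file.path(out, "exposure_vkmt.csv"))

rates <- rbind(monthly_rates(collisions, pop, "population"),
               monthly_rates(collisions, vk, "vkmt"))
summ <- yearly_summary(rates)
utils::write.csv(rates, file.path(out, "rates_monthly.csv"), row.names = FALSE)
utils::write.csv(summ, file.path(out, "rates_yearly.csv"), row.names = FALSE)

for (oc in c("nonfatal", "fatal")) for (dk in c("population", "vkmt")) {
  sub <- rates[rates$outcome == oc & rates$denominator_kind == dk, ]
  r <- compare_years(sub, 2011, 2017, by_sex = TRUE)
  message(sprintf("%s per %s: change 2011->2017 = %.0f%% (p = %.3g), sex difference p = %.3g",
                  oc, dk, r$pct_change, r$p_value, r$sex_diff_p))
}

sm <- smr(collisions, pop)
utils::write.csv(sm$panel, file.path(out, "smr_monthly.csv"), row.names = FALSE)
utils::write.csv(sm$yearly, file.path(out, "smr_yearly.csv"), row.names = FALSE)
ys <- sm$yearly[sm$yearly$sex == "all", ]
message(sprintf("mean monthly SMR: %.2f (2011) -> %.2f (2017), reduction %.0f%%",
                ys$mean_smr[ys$year == 2011], ys$mean_smr[ys$year == 2017],
                percent_change(ys$mean_smr[ys$year == 2011],
                               ys$mean_smr[ys$year == 2017])))
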