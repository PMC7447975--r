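#!/usr/bin/env Rscript
# Stage 2 — exposure denominators.
#
# Expands the weighted surveys into per-zone bicyclist population and
# daily kilometers traveled (Horvitz-Thompson expansion, shortest-path
# routing, polygon allocation), fills the analysis years by stratified
# linear interpolation/extrapolation, and reports the validation error of
# the kilometer estimates against the stored ground truth.

library(cyclesafe)

out <- "results/synthetic"
zones <- read_zones_geojson(file.path(out, "zones.geojson"))
network <- read_network_geojson(file.path(out, "network.geojson"))
surveys <- read_surveys(file.path(out, "surveys.csv"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                             simplifyVector = TRUE)

message("expanding person records ...")
pop <- estimate_population(surveys,
                           zone_ids = vapply(zones$zones, `[[`,
                                             character(1), "zone_id"))
pop_full <- interpolate_panel(pop, 2011:2017)

message("routing trip flows and allocating kilometers ...")
vk <- estimate_vkmt(surveys, zones, network)
vk_full <- interpolate_panel(vk, 2011:2017)

write_exposure(pop_full, file.path(out, "exposure_population.csv"))
write_exposure(vk_full, file.path(out, "exposure_vkmt.csv"))

# validation against truth, mirroring the survey-based error assessment
y <- max(vk$year)
tru <- truth$true_vkmt[truth$true_vkmt$year == y, ]
est <- vk[vk$year == y, ]
m <- merge(est, tru, by = "zone_id")
v <- validation_error(m$daily_vkmt.y, m$daily_vkmt.x)
message(sprintf("daily-kilometer validation, year %d: total error %.1f%%, mean stratified error %.1f%% over %d zones (%d empty excluded)",
                y, v$total_pct_error, v$mean_stratified_pct_error,
                v$n_groups, v$n_excluded))
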