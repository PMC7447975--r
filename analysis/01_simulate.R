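#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study city.
#
# Generates a 100-zone, 20 x 20 km city with a lattice road network, five
# survey waves (2005, 2011, 2014, 2015, 2017) under a three-fold
# bicyclist-growth scenario, and a seven-year collision registry of 9950
# events (~3.6% fatal plus three planted fatal hotspots), then writes the
# raw inputs every later stage consumes.

library(cyclesafe)

seed <- 20110101 %% 2147483647
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("generating city ...")
city <- generate_city(100, c(0, 0, 20000, 20000), seed = seed)

message("laying down ground truth (population, flows, kilometers, risk) ...")
truth <- make_ground_truth(city, seed = seed)

message("drawing surveys and collisions ...")
surveys <- generate_surveys(city$zones, seed = seed, truth = truth)
collisions <- generate_collisions(city$zones, city$network, truth, seed = seed)

write_zones_geojson(city$zones, file.path(out, "zones.geojson"))
write_network_geojson(city$network, file.path(out, "network.geojson"))
write_surveys(surveys, file.path(out, "surveys.csv"))
write_collisions(collisions, file.path(out, "collisions.csv"))
write_ground_truth(truth, file.path(out, "ground_truth.json"))

message(sprintf("city: %d zones | %d survey records | %d collisions (%.1f%% fatal)",
                length(city$zones$zones),
                sum(vapply(surveys, nrow, 1L)),
                nrow(collisions), 100 * mean(collisions$fatal)))
message("wrote raw inputs to ", out)
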