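#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 27-cruise survey — environmental fields,
# transect effort and sightings, CTD stations, climate indices and activity
# footprints — and write the raw data products.

suppressPackageStartupMessages(library(pelagicplan))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dir.create("results/cache", showWarnings = FALSE, recursive = TRUE)
dir.create("results/raw", showWarnings = FALSE, recursive = TRUE)

region <- default_region(27)
cfg <- sim_config(seed = seed)
sim <- simulate_survey(cfg, region)

write.csv(sim$survey$effort, "results/raw/effort.csv", row.names = FALSE)
write.csv(sim$survey$sightings, "results/raw/sightings.csv", row.names = FALSE)
write.csv(sim$ctd, "results/raw/ctd.csv", row.names = FALSE)
write.csv(sim$indices$monthly, "results/raw/indices_monthly.csv", row.names = FALSE)
write.csv(sim$indices$daily, "results/raw/upwelling_daily.csv", row.names = FALSE)
write_region_geojson(region, "results/raw/region.geojson")
write_activities_geojson(sim$activities, "results/raw/activities.geojson")
jsonlite::write_json(unclass(cfg), "results/raw/config.json",
                     auto_unbox = TRUE, digits = NA)
saveRDS(sim, "results/cache/sim.rds")

cat(sprintf("Simulated %d cruises: %d effort segments, %d sighting records,\n",
            nrow(region$calendar), nrow(sim$survey$effort),
            nrow(sim$survey$sightings)))
cat(sprintf("%d CTD records across %d stations; %d cruises lack SSF.\n",
            nrow(sim$ctd), length(unique(sim$ctd$station_id)),
            sum(sim$survey$cruises$ssf_missing)))
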