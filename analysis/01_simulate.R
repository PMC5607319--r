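#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study emulating the sampling design:
# three grassland communities (south-facing slope, north-facing slope, flat
# hay meadow) x 35 fenced plots x 12 observation times over one growing
# season, the flat community unsampled at times 8-9 (hay mowing), plus a
# synthetic year of daily weather. Writes the study CSV set under
# results/study/.

library(traitbloom)

seed <- 2011L
cfg <- synthetic_config(seed = seed)
study <- generate_study(cfg)
print(study)

dir.create("results/study", recursive = TRUE, showWarnings = FALSE)
write_study(study, "results/study")
utils::write.table(attr(study, "ground_truth"),
                   "results/study/ground_truth.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

climate <- generate_climate(seed = seed)
utils::write.table(climate, "results/study/climate_daily.csv", sep = ",",
                   row.names = FALSE, quote = FALSE)

message(sprintf(
  "study: %d plots, %d species observed flowering, %d observation rows",
  nrow(study$plots), length(unique(study$observations$species_id)),
  nrow(study$observations)
))
message(sprintf("daily weather: %d days, %.0f mm annual precipitation",
                nrow(climate), sum(climate$precipitation)))
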