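#!/usr/bin/env Rscript
# Step 2 — aggregate shoot counts into the releves-by-trait-states matrix
# of mean flowering proportions, and summarise: descriptive statistics of F
# per community x time x trait state, seasonal environmental trends per
# community, and monthly climate.

library(traitbloom)

study <- read_study("results/study")
tm <- build_trait_matrix(study)
print(tm)

stats <- descriptive_stats(tm)
envsum <- env_seasonal_summary(study$env, study$plots)
climate <- utils::read.csv("results/study/climate_daily.csv")
monthly <- summarize_climate(climate)

fm <- cbind(releve = rownames(tm$F), as.data.frame(tm$F))
write_results(
  list(trait_matrix = fm, descriptive_stats = stats,
       env_summary = envsum, climate_monthly = monthly),
  "results/tables"
)

message(sprintf("matrix: %d releves x %d trait states", nrow(tm$F), ncol(tm$F)))
message(sprintf("F range %.3f-%.3f; %.1f%% of cells have flowering",
                min(tm$F), max(tm$F), 100 * mean(tm$F > 0)))
for (cm in unique(envsum$community)) {
  e <- envsum[envsum$community == cm, ]
  message(sprintf(
    "%6s: soil T %.1f-%.1f C, humidity %.0f-%.0f%%, canopy up to %.0f cm",
    cm, min(e$temp_mean), max(e$temp_mean), min(e$hum_mean),
    max(e$hum_mean), max(e$canopy_mean)))
}
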