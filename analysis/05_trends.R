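#!/usr/bin/env Rscript
# Step 5 — linear mixed-effects trend models: for every trait state, one
# model on the whole data set (fixed candidates soil temperature, soil
# relative humidity, canopy height, time, topographic position) and one per
# community subset (without topographic position), reduced by backward
# elimination on likelihood-ratio tests and compared against the
# random-effects-only null model.

library(traitbloom)

study <- read_study("results/study")
tm <- build_trait_matrix(study)

t0 <- Sys.time()
models <- run_all_models(tm, study, alpha = 0.05)
write_results(list(trend_models = models), "results/tables")

ok <- !is.na(models$p)
message(sprintf("fitted %d of %d trait-state x scope models in %s",
                sum(ok), nrow(models), format(Sys.time() - t0, digits = 3)))
message(sprintf("significant full-vs-null comparisons: %d (***: %d, **: %d, *: %d)",
                sum(models$signif[ok] != "n.s."),
                sum(models$signif[ok] == "***"),
                sum(models$signif[ok] == "**"),
                sum(models$signif[ok] == "*")))
tab <- table(unlist(strsplit(models$model[ok & models$model != "(none)"],
                             " \\+ ")))
message("retained fixed effects across models: ",
        paste(sprintf("%s x%d", names(tab), tab), collapse = ", "))
if (any(!ok)) {
  message("skipped models: ",
          paste(unique(models$note[!ok]), collapse = " | "))
}
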