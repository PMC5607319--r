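# Pipeline orchestration: aggregate -> descriptive stats -> ISA ->
# RDA/variation partitioning -> mixed-effects trend models, with a run
# manifest. Also the climate and environmental summary helpers.

#' Pipeline configuration
#'
#' Defaults are the analysis' reference settings: retention filters
#' RA >= 0.6 and RF >= 0.25 at alpha = 0.05, 4999 ISA permutations, 999 RDA
#' permutations, candidate time groups up to 3 times.
#'
#' @param out_dir Output directory for result tables and the manifest.
#' @param alpha,ra_min,rf_min ISA significance level and retention filters.
#' @param n_perm_isa,n_perm_rda Permutation counts.
#' @param max_order Largest candidate time-group size.
#' @param seed Integer seed governing all pipeline randomness.
#' @param stages Character vector of stages to run, a subset of
#'   `c("aggregate", "stats", "isa", "rda", "lmm")` (`aggregate` is always
#'   implied).
#' @param lmm_states Optional data frame (`trait`, `state`) restricting the
#'   trend-model responses (the slowest stage).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "results",
                            alpha = 0.05, ra_min = 0.6, rf_min = 0.25,
                            n_perm_isa = 4999, n_perm_rda = 999,
                            max_order = 3, seed = 1L,
                            stages = c("aggregate", "stats", "isa", "rda",
                                       "lmm"),
                            lmm_states = NULL) {
  structure(list(
    out_dir = out_dir, alpha = alpha, ra_min = ra_min, rf_min = rf_min,
    n_perm_isa = n_perm_isa, n_perm_rda = n_perm_rda,
    max_order = max_order, seed = as.integer(seed), stages = stages,
    lmm_states = lmm_states
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline on a study
#'
#' Stages run in order (aggregation, descriptive statistics, indicator
#' analysis, RDA with variation partitioning, trend models); each enabled
#' stage writes its result table(s) under `config$out_dir`, and a manifest
#' records parameters, seed and an MD5 checksum per output file. Identical
#' study + config implies byte-identical outputs.
#'
#' @param study A validated `flowering_study`.
#' @param config A [pipeline_config()].
#' @return Named list of in-memory results (`matrix`, `stats`, `isa`,
#'   `rda`, `varpart`, `lmm`, `manifest`), invisibly.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  tables <- list()

  tm <- build_trait_matrix(study)
  res$matrix <- tm
  fm <- as.data.frame(tm$F)
  fm <- cbind(releve = rownames(tm$F), fm)
  tables$trait_matrix <- fm

  if ("stats" %in% config$stages) {
    res$stats <- descriptive_stats(tm)
    tables$descriptive_stats <- res$stats
    res$env_summary <- env_seasonal_summary(study$env, study$plots)
    tables$env_summary <- res$env_summary
  }
  if ("isa" %in% config$stages) {
    res$isa <- run_isa(tm, alpha = config$alpha, ra_min = config$ra_min,
                       rf_min = config$rf_min, n_perm = config$n_perm_isa,
                       max_order = config$max_order, seed = config$seed)
    tables$indicator_trait_states <- res$isa
  }
  if ("rda" %in% config$stages) {
    axes <- list()
    parts <- list()
    res$rda <- list()
    res$varpart <- list()
    for (cm in unique(tm$rows$community)) {
      bl <- predictor_blocks(tm, study, cm)
      fit <- rda_fit(bl$Y, cbind(bl$time, bl$env))
      vp <- variation_partition(bl$Y, bl$time, bl$env,
                                n_perm = config$n_perm_rda,
                                seed = config$seed)
      res$rda[[cm]] <- fit
      res$varpart[[cm]] <- vp
      k <- seq_along(fit$eig)
      axes[[cm]] <- data.frame(
        community = cm, axis = k,
        pct_total = round(fit$pct_total, 6),
        pct_constrained = round(fit$pct_constrained, 6),
        stringsAsFactors = FALSE
      )
      pt <- varpart_table(vp)
      pt <- cbind(community = cm, pt)
      parts[[cm]] <- pt
    }
    tables$rda_axes <- do.call(rbind, axes)
    tables$variation_partition <- do.call(rbind, parts)
  }
  if ("lmm" %in% config$stages) {
    res$lmm <- run_all_models(tm, study, states = config$lmm_states,
                              alpha = config$alpha)
    tables$trend_models <- res$lmm
  }

  paths <- write_results(tables, config$out_dir, format = "tsv")
  manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE
  )
  params <- data.frame(
    file = "(parameters)",
    md5 = sprintf(
      "alpha=%g ra_min=%g rf_min=%g n_perm_isa=%d n_perm_rda=%d max_order=%d seed=%d",
      config$alpha, config$ra_min, config$rf_min, config$n_perm_isa,
      config$n_perm_rda, config$max_order, config$seed
    ),
    stringsAsFactors = FALSE
  )
  manifest <- rbind(params, manifest)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  res$manifest <- manifest
  res$tables <- tables
  invisible(res)
}

#' Monthly climate summary from daily records
#'
#' @param daily Data frame with columns `date`, `temperature`,
#'   `precipitation`.
#' @return Data frame with one row per month having data: `month`
#'   (`"YYYY-MM"`), `mean_temperature`, `total_precipitation`, `n_days`
#'   (coverage).
#' @export
summarize_climate <- function(daily) {
  need <- c("date", "temperature", "precipitation")
  missing <- setdiff(need, names(daily))
  if (length(missing) > 0) {
    tb_error("tb_schema_error", sprintf(
      "daily climate table missing column(s): %s",
      paste(missing, collapse = ", ")))
  }
  keep <- !is.na(daily$date)
  daily <- daily[keep, , drop = FALSE]
  mon <- format(as.Date(daily$date), "%Y-%m")
  sp_t <- split(daily$temperature, mon)
  sp_p <- split(daily$precipitation, mon)
  data.frame(
    month = names(sp_t),
    mean_temperature = vapply(sp_t, function(v) mean(v, na.rm = TRUE), 0),
    total_precipitation = vapply(sp_p, function(v) sum(v, na.rm = TRUE), 0),
    n_days = lengths(sp_t),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Seasonal summary of environmental variables per community
#'
#' @param env Environmental records (`plot_id`, `time_index`,
#'   `soil_temperature`, `soil_relative_humidity`, `canopy_height`).
#' @param plots Plot metadata (`plot_id`, `community`).
#' @return Data frame with one row per community x observed time: means and
#'   standard deviations of the three variables over plots.
#' @export
env_seasonal_summary <- function(env, plots) {
  comm <- plots$community[match(env$plot_id, plots$plot_id)]
  grp <- paste(comm, env$time_index, sep = "\r")
  agg <- function(v, f) vapply(split(v, grp), f, 0)
  lab <- do.call(rbind, strsplit(names(split(env$time_index, grp)), "\r"))
  out <- data.frame(
    community = lab[, 1],
    time_index = as.integer(lab[, 2]),
    temp_mean = agg(env$soil_temperature, mean),
    temp_sd = agg(env$soil_temperature, stats::sd),
    hum_mean = agg(env$soil_relative_humidity, mean),
    hum_sd = agg(env$soil_relative_humidity, stats::sd),
    canopy_mean = agg(env$canopy_height, mean),
    canopy_sd = agg(env$canopy_height, stats::sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[order(out$community, out$time_index), ]
}
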