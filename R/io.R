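# Domain types, readers/writers and validation shared by all pipeline stages.
#
# A study is a plain list of five data frames plus a skip table:
#   observations : plot_id, time_index, species_id, shoots_in_full_bloom
#   traits       : species_id, trait, state   (long, one state per species x trait)
#   env          : plot_id, time_index, soil_temperature, soil_relative_humidity,
#                  canopy_height
#   plots        : plot_id, community
#   times        : time_index, calendar_label
#   skips        : community, time_index     (times not sampled in a community)

tb_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "tb_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Calendar of the emulated growing-season observation times
#'
#' Twelve biweekly-to-monthly observation dates spanning a single growing
#' season (early April to late October). Used as the default time calendar by
#' the synthetic-study generator.
#'
#' @return A data frame with columns `time_index` (1..12) and
#'   `calendar_label`.
#' @export
default_calendar <- function() {
  data.frame(
    time_index = 1:12,
    calendar_label = c(
      "4 Apr", "18 Apr", "2 May", "16 May", "30 May", "13 Jun",
      "30 Jun", "20 Jul", "5 Aug", "19 Aug", "6 Sep", "21 Oct"
    ),
    stringsAsFactors = FALSE
  )
}

#' Assemble and validate a flowering study
#'
#' Bundles the five study tables into a validated `flowering_study` object.
#' Zero-count observation rows are dropped (a zero count is semantically
#' identical to an absent row), and referential integrity is enforced: every
#' species observed flowering must appear in the trait table, every observed
#' plot must have metadata, and every (plot, observed time) must carry exactly
#' one environmental record.
#'
#' @param observations Data frame with columns `plot_id`, `time_index`,
#'   `species_id`, `shoots_in_full_bloom`.
#' @param traits Long data frame with columns `species_id`, `trait`, `state`.
#' @param env Data frame with columns `plot_id`, `time_index`,
#'   `soil_temperature` (degrees C), `soil_relative_humidity` (percent,
#'   0-100), `canopy_height` (cm, non-negative).
#' @param plots Data frame with columns `plot_id`, `community`.
#' @param times Data frame with columns `time_index`, `calendar_label`.
#' @param skips Optional data frame with columns `community`, `time_index`
#'   listing observation times not sampled in a community (e.g. mowing
#'   dates); defaults to no skips.
#' @return An object of class `flowering_study`.
#' @export
flowering_study <- function(observations, traits, env, plots, times,
                            skips = NULL) {
  if (is.null(skips)) {
    skips <- data.frame(community = character(), time_index = integer())
  }
  study <- structure(
    list(
      observations = as.data.frame(observations),
      traits = as.data.frame(traits),
      env = as.data.frame(env),
      plots = as.data.frame(plots),
      times = as.data.frame(times),
      skips = as.data.frame(skips)
    ),
    class = "flowering_study"
  )
  validate_study(study)
}

required_study_columns <- function() {
  list(
    observations = c("plot_id", "time_index", "species_id",
                     "shoots_in_full_bloom"),
    traits = c("species_id", "trait", "state"),
    env = c("plot_id", "time_index", "soil_temperature",
            "soil_relative_humidity", "canopy_height"),
    plots = c("plot_id", "community"),
    times = c("time_index", "calendar_label"),
    skips = c("community", "time_index")
  )
}

check_columns <- function(df, name) {
  need <- required_study_columns()[[name]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    tb_error("tb_schema_error", sprintf(
      "table '%s' is missing column(s): %s", name,
      paste(missing, collapse = ", ")
    ))
  }
  df[need]
}

#' Observation times sampled in a community
#'
#' @param study A `flowering_study`.
#' @param community Community label.
#' @return Sorted integer vector of time indices sampled in that community.
#' @export
observed_times <- function(study, community) {
  skip <- study$skips$time_index[study$skips$community == community]
  sort(setdiff(study$times$time_index, skip))
}

#' Validate a flowering study
#'
#' Checks schema, type invariants and referential integrity; normalizes the
#' sparse representation by dropping zero-count observation rows. Called by
#' [flowering_study()] and [read_study()].
#'
#' @param study A `flowering_study`-shaped list.
#' @return The validated (normalized) study, invisibly classed
#'   `flowering_study`.
#' @export
validate_study <- function(study) {
  for (nm in c("observations", "traits", "env", "plots", "times", "skips")) {
    study[[nm]] <- check_columns(as.data.frame(study[[nm]]), nm)
  }
  obs <- study$observations
  obs$time_index <- as.integer(obs$time_index)
  obs$shoots_in_full_bloom <- as.integer(obs$shoots_in_full_bloom)
  tms <- study$times
  tms$time_index <- as.integer(tms$time_index)

  if (nrow(tms) < 2 || anyDuplicated(tms$time_index) ||
      any(diff(tms$time_index) <= 0)) {
    tb_error("tb_schema_error",
             "times must have >= 2 strictly increasing unique indices")
  }
  if (anyDuplicated(study$plots$plot_id)) {
    tb_error("tb_duplication_error", "duplicate plot_id in plot metadata")
  }
  key <- paste(study$traits$species_id, study$traits$trait)
  if (anyDuplicated(key)) {
    tb_error("tb_duplication_error", sprintf(
      "multiple states for the same (species, trait): %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    ))
  }
  if (any(is.na(obs$shoots_in_full_bloom)) ||
      any(obs$shoots_in_full_bloom < 0)) {
    tb_error("tb_schema_error", "shoot counts must be non-negative integers")
  }
  # normalize: zero-count rows are identical to absent rows
  obs <- obs[obs$shoots_in_full_bloom > 0, , drop = FALSE]
  okey <- paste(obs$plot_id, obs$time_index, obs$species_id)
  if (anyDuplicated(okey)) {
    tb_error("tb_duplication_error", sprintf(
      "duplicate (plot, time, species) observation rows: %s",
      paste(utils::head(unique(okey[duplicated(okey)]), 5), collapse = "; ")
    ))
  }
  unknown_sp <- setdiff(obs$species_id, study$traits$species_id)
  if (length(unknown_sp) > 0) {
    tb_error("tb_integrity_error", sprintf(
      "species observed but absent from the trait table: %s",
      paste(unknown_sp, collapse = ", ")
    ))
  }
  unknown_plot <- setdiff(obs$plot_id, study$plots$plot_id)
  if (length(unknown_plot) > 0) {
    tb_error("tb_integrity_error", sprintf(
      "plots observed but absent from plot metadata: %s",
      paste(unknown_plot, collapse = ", ")
    ))
  }
  bad_time <- setdiff(obs$time_index, tms$time_index)
  if (length(bad_time) > 0) {
    tb_error("tb_integrity_error", sprintf(
      "observation time indices outside the calendar: %s",
      paste(bad_time, collapse = ", ")
    ))
  }
  # observations must fall on the sampled times of the plot's community
  comm_of <- stats::setNames(study$plots$community, study$plots$plot_id)
  study$times <- tms
  study$observations <- obs
  class(study) <- "flowering_study"
  for (cm in unique(study$plots$community)) {
    ot <- observed_times(study, cm)
    in_cm <- obs$plot_id %in% study$plots$plot_id[study$plots$community == cm]
    off <- setdiff(unique(obs$time_index[in_cm]), ot)
    if (length(off) > 0) {
      tb_error("tb_integrity_error", sprintf(
        "community '%s' has observations at skipped time(s): %s",
        cm, paste(off, collapse = ", ")
      ))
    }
  }
  # environmental covariates must be complete: one record per (plot, time)
  env <- study$env
  env$time_index <- as.integer(env$time_index)
  ekey <- paste(env$plot_id, env$time_index)
  if (anyDuplicated(ekey)) {
    tb_error("tb_duplication_error",
             "duplicate (plot, time) environmental records")
  }
  if (any(env$soil_relative_humidity < 0 | env$soil_relative_humidity > 100,
          na.rm = TRUE)) {
    tb_error("tb_schema_error", "soil_relative_humidity outside [0, 100]")
  }
  if (any(env$canopy_height < 0, na.rm = TRUE)) {
    tb_error("tb_schema_error", "canopy_height must be >= 0")
  }
  for (p in study$plots$plot_id) {
    ot <- observed_times(study, comm_of[[p]])
    have <- env$time_index[env$plot_id == p]
    miss <- setdiff(ot, have)
    if (length(miss) > 0) {
      tb_error("tb_integrity_error", sprintf(
        "plot '%s' lacks environmental records at time(s): %s",
        p, paste(miss, collapse = ", ")
      ))
    }
  }
  study$env <- env
  invisible(study)
}

#' @export
print.flowering_study <- function(x, ...) {
  cat(sprintf(
    "flowering_study: %d plots, %d communities, %d times, %d species, %d observation rows\n",
    nrow(x$plots), length(unique(x$plots$community)), nrow(x$times),
    length(unique(x$traits$species_id)), nrow(x$observations)
  ))
  invisible(x)
}

study_tables <- c("observations", "traits", "env", "plots", "times", "skips")

#' Read a flowering study from delimited files
#'
#' @param paths Named character vector or list with elements `observations`,
#'   `traits`, `env`, `plots`, `times` and optionally `skips`, each a path to
#'   a delimited text file with a header row. Alternatively a single
#'   directory containing files named `<table>.csv` (or `.tsv`).
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return A validated `flowering_study`.
#' @export
read_study <- function(paths, delim = ",") {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths[[1]])) {
    ext <- if (delim == ",") "csv" else "tsv"
    paths <- stats::setNames(
      file.path(paths[[1]], paste0(study_tables, ".", ext)), study_tables
    )
    paths <- paths[file.exists(paths)]
  }
  need <- setdiff(study_tables, "skips")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) {
    tb_error("tb_schema_error", sprintf(
      "read_study needs paths for: %s", paste(missing, collapse = ", ")
    ))
  }
  for (nm in intersect(study_tables, names(paths))) {
    if (!file.exists(paths[[nm]])) {
      tb_error("tb_schema_error",
               sprintf("file not found for '%s': %s", nm, paths[[nm]]))
    }
  }
  rd <- function(p) utils::read.table(p, header = TRUE, sep = delim,
                                      stringsAsFactors = FALSE, quote = "\"")
  tabs <- lapply(paths[intersect(study_tables, names(paths))], rd)
  flowering_study(tabs$observations, tabs$traits, tabs$env, tabs$plots,
                  tabs$times, skips = tabs$skips)
}

#' Read a study via a plain-text configuration file
#'
#' The YAML config declares the table paths and delimiter:
#' `delim: ","` and a `paths:` mapping with one entry per table.
#' Relative paths are resolved against the config file's directory.
#'
#' @param config_path Path to the YAML configuration file.
#' @return A validated `flowering_study`.
#' @export
read_study_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$paths)) {
    tb_error("tb_schema_error", "study config lacks a 'paths' mapping")
  }
  base <- dirname(normalizePath(config_path))
  paths <- lapply(cfg$paths, function(p) {
    if (file.exists(p)) p else file.path(base, p)
  })
  read_study(paths, delim = cfg$delim %||% ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a flowering study to delimited files
#'
#' @param study A `flowering_study`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir, delim = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (delim == ",") "csv" else "tsv"
  paths <- character(0)
  for (nm in study_tables) {
    p <- file.path(dir, paste0(nm, ".", ext))
    utils::write.table(study[[nm]], p, sep = delim, row.names = FALSE,
                       quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

# serialized display precision per column name pattern (matches the
# reporting style of the source tables: IV/RA/RF/p to 3 decimals,
# variance fractions as percentages to 1 decimal)
result_precision <- function(colname) {
  if (colname %in% c("iv", "ra", "rf", "p_value", "p")) return(3L)
  if (grepl("_pct$", colname)) return(1L)
  NA_integer_
}

#' Write result tables with fixed display precision
#'
#' Indicator-value components (`iv`, `ra`, `rf`, `p_value`) are serialized to
#' 3 decimals and percentage columns (suffix `_pct`) to 1 decimal; other
#' numeric columns are written at full precision.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv"` or `"csv"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      tb_error("tb_io_error", sprintf("cannot create '%s'", out_dir))
    }
  }
  sep <- if (format == "tsv") "\t" else ","
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (cn in names(df)) {
      dg <- result_precision(cn)
      if (!is.na(dg) && is.numeric(df[[cn]])) df[[cn]] <- round(df[[cn]], dg)
    }
    p <- file.path(out_dir, paste0(nm, ".", format))
    utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
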