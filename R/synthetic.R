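# Synthetic-study generator: emulates a single-season trait-based flowering
# survey over three topographic grassland communities (south-facing slope,
# north-facing slope, flat hay meadow), 35 fenced plots each, observed at 12
# times, the flat community skipping the two mowing dates.

#' Default functional-trait vocabulary
#'
#' Eight categorical traits spanning resource-acquisition and
#' stress-tolerance strategies (life span, vegetative propagation, storage
#' organ, leaf persistence, leaf anatomy, horizontal and vertical space
#' occupation, plant height class).
#'
#' @return Named list mapping trait name to its character vector of states.
#' @export
default_trait_vocabulary <- function() {
  list(
    life_span = c("annual", "biennial", "perennial"),
    vegetative_propagation = c("absent", "bulbils", "runner", "rhizome"),
    storage_organ = c("absent", "bulb", "tuber", "tap_root"),
    leaf_persistence = c("persistent_green", "spring_green", "summer_green",
                         "overwintering_green"),
    leaf_anatomy = c("succulent", "hygromorphic", "mesomorphic",
                     "scleromorphic"),
    horizontal_space = c("absent", "caespitose", "pleiocorm", "rosette"),
    vertical_space = c("grass", "rosette_forb", "upright_forb",
                       "prostrate_forb"),
    height_class = c("h_20", "h_40", "h_60", "h_80")
  )
}

#' Configuration for a synthetic flowering study
#'
#' Defaults encode the emulated design: 3 communities x 35 plots x 12
#' observation times, with the flat community skipping times 8 and 9 (hay
#' mowing). Per-species unimodal (Gaussian) flowering curves are discretized
#' over the observation indices; seasonal shoot totals are overdispersed
#' (negative binomial). Flowering-curve widths default to 0.45-0.9
#' observation intervals: with roughly biweekly sampling, a bloom lasting two
#' to four weeks concentrates its shoots on one to three adjacent times while
#' always giving non-negligible mass to at least two indices.
#'
#' @param n_communities Number of communities (default 3; labels from
#'   `communities`).
#' @param communities Community labels.
#' @param plots_per_community Plots per community (default 35).
#' @param n_times Number of observation times (default 12).
#' @param skipped_times Named list: community -> integer vector of unsampled
#'   times (default: flat skips 8 and 9).
#' @param species_pool_size Species per community (default 40).
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters for the
#'   expected per-plot seasonal shoot total of a species.
#' @param dispersion Negative-binomial size parameter for seasonal totals
#'   (smaller = more clumped).
#' @param sigma_range Range of flowering-curve widths (observation-interval
#'   units; both endpoints > 0).
#' @param planted_sigma_range Curve-width range redrawn for carriers whose
#'   peak is concentrated into a planted group (synchronized short blooms,
#'   so the bloom actually fits inside a 1-3 time group).
#' @param mu_range Range of flowering peak times (defaults to the full
#'   season, `c(1, n_times)`).
#' @param trait_vocabulary Named list of trait -> states.
#' @param planted_indicators List of planted indicators, each a list with
#'   `trait`, `state`, `group` (integer time indices) and `strength` in
#'   [0, 1]: a carrier species' peak is drawn inside the group with
#'   probability `strength`.
#' @param env Environmental-trajectory parameters; see
#'   [default_env_params()].
#' @param rebloom Optional post-mowing re-bloom in the flat community
#'   (off by default).
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_communities = 3,
                             communities = c("south", "north", "flat"),
                             plots_per_community = 35,
                             n_times = 12,
                             skipped_times = list(flat = c(8L, 9L)),
                             species_pool_size = 40,
                             abundance_meanlog = log(15),
                             abundance_sdlog = 0.6,
                             dispersion = 1.5,
                             sigma_range = c(0.45, 0.9),
                             planted_sigma_range = c(0.25, 0.45),
                             mu_range = NULL,
                             trait_vocabulary = default_trait_vocabulary(),
                             planted_indicators = list(),
                             env = default_env_params(),
                             rebloom = FALSE,
                             seed = 1L) {
  if (is.null(mu_range)) mu_range <- c(1, n_times)
  cfg <- structure(
    list(
      n_communities = n_communities,
      communities = communities[seq_len(n_communities)],
      plots_per_community = plots_per_community,
      n_times = as.integer(n_times),
      skipped_times = skipped_times,
      species_pool_size = species_pool_size,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      dispersion = dispersion,
      sigma_range = sigma_range,
      planted_sigma_range = planted_sigma_range,
      mu_range = mu_range,
      trait_vocabulary = trait_vocabulary,
      planted_indicators = planted_indicators,
      env = env,
      rebloom = rebloom,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$sigma_range <= 0)) {
    tb_error("tb_config_error", "flowering-curve widths must be > 0")
  }
  if (cfg$n_times < 2) {
    tb_error("tb_config_error", "need at least 2 observation times")
  }
  if (cfg$dispersion <= 0) {
    tb_error("tb_config_error", "dispersion must be > 0")
  }
  for (cm in names(cfg$skipped_times)) {
    if (!cm %in% cfg$communities) {
      tb_error("tb_config_error", sprintf("skip list names unknown community '%s'", cm))
    }
    if (any(!cfg$skipped_times[[cm]] %in% seq_len(cfg$n_times))) {
      tb_error("tb_config_error", "skipped times outside the calendar")
    }
  }
  vocab <- cfg$trait_vocabulary
  for (pl in cfg$planted_indicators) {
    if (is.null(vocab[[pl$trait]]) || !pl$state %in% vocab[[pl$trait]]) {
      tb_error("tb_config_error", sprintf(
        "planted indicator names unknown trait state %s=%s", pl$trait, pl$state
      ))
    }
    if (any(!pl$group %in% seq_len(cfg$n_times))) {
      tb_error("tb_config_error", "planted time group outside observed times")
    }
    if (pl$strength < 0 || pl$strength > 1) {
      tb_error("tb_config_error", "planted strength must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

#' Default environmental-trajectory parameters
#'
#' Soil temperature rises to a mid-summer peak and falls (south community
#' warmest); soil relative humidity declines from a moist spring to the
#' summer drought with a slight autumn recovery (flat community moistest);
#' canopy grows over the season to a community-specific maximum, and in the
#' flat (mown) community is reset to a few centimetres after the mowing
#' dates. Noise is independent per (plot, time).
#'
#' @param temp_base,temp_amplitude Seasonal soil-temperature curve (degrees
#'   C): `base + amplitude * sin(pi * (t - 1) / (g - 1))`.
#' @param temp_offsets Named per-community additive offsets (degrees C).
#' @param hum_start,hum_end Humidity (%) at season start/end before the
#'   autumn recovery term.
#' @param hum_autumn_recovery Humidity added over the last two times.
#' @param hum_offsets Named per-community offsets (%).
#' @param canopy_max Named per-community canopy asymptote (cm).
#' @param canopy_rate Logistic growth rate of canopy per observation step.
#' @param mow_reset_height Canopy (cm) right after mowing in the flat
#'   community.
#' @param noise_sd Named list of observation noise standard deviations
#'   (`temp` degrees C, `hum` %, `canopy` cm).
#' @return A list of parameters consumed by [generate_env()].
#' @export
default_env_params <- function(temp_base = 7,
                               temp_amplitude = 14,
                               temp_offsets = c(south = 2.5, north = 0, flat = 1),
                               hum_start = 70,
                               hum_end = 12,
                               hum_autumn_recovery = 15,
                               hum_offsets = c(south = 0, north = 6, flat = 14),
                               canopy_max = c(south = 18, north = 32, flat = 55),
                               canopy_rate = 0.9,
                               mow_reset_height = 3,
                               noise_sd = list(temp = 1.2, hum = 4, canopy = 2)) {
  list(
    temp_base = temp_base, temp_amplitude = temp_amplitude,
    temp_offsets = temp_offsets,
    hum_start = hum_start, hum_end = hum_end,
    hum_autumn_recovery = hum_autumn_recovery, hum_offsets = hum_offsets,
    canopy_max = canopy_max, canopy_rate = canopy_rate,
    mow_reset_height = mow_reset_height, noise_sd = noise_sd
  )
}

# trait-state frequencies decline with list position: the leading state of
# each trait is the common syndrome, later states are progressively rarer
# specialized guilds (geometric weights, ratio 0.55)
state_weights <- function(k) {
  w <- 0.55^(seq_len(k) - 1)
  w / sum(w)
}

# deterministic per-community species pool: ids, trait states, flowering
# curves (depends only on cfg and the RNG state)
draw_species_pool <- function(cfg, community) {
  n <- cfg$species_pool_size
  ids <- sprintf("%s_sp%02d", community, seq_len(n))
  vocab <- cfg$trait_vocabulary
  traits <- do.call(rbind, lapply(names(vocab), function(tr) {
    data.frame(
      species_id = ids,
      trait = tr,
      state = sample(vocab[[tr]], n, replace = TRUE,
                     prob = state_weights(length(vocab[[tr]]))),
      stringsAsFactors = FALSE
    )
  }))
  mu <- stats::runif(n, cfg$mu_range[1], cfg$mu_range[2])
  sigma <- stats::runif(n, cfg$sigma_range[1], cfg$sigma_range[2])
  nu <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
  # planted indicators: carriers concentrate their peak inside the group
  for (pl in cfg$planted_indicators) {
    if (pl$strength == 0) next  # exact reduction to the null generator
    carriers <- traits$species_id[traits$trait == pl$trait &
                                    traits$state == pl$state]
    idx <- match(carriers, ids)
    for (i in idx) {
      if (stats::runif(1) < pl$strength) {
        centre <- pl$group[sample.int(length(pl$group), 1)]
        mu[i] <- centre + stats::runif(1, -0.3, 0.3)
        # a concentrated carrier blooms synchronously: its curve width is
        # redrawn so the bloom actually sits inside the planted group
        sigma[i] <- stats::runif(1, cfg$planted_sigma_range[1],
                                 cfg$planted_sigma_range[2])
      }
    }
  }
  list(ids = ids, traits = traits, mu = mu, sigma = sigma, nu = nu)
}

#' Generate a complete synthetic flowering study
#'
#' Per species and plot, a seasonal shoot total is drawn from a negative
#' binomial with the species' expected abundance, then allocated across the
#' plot's observed times by a multinomial whose probabilities follow a
#' discretized Gaussian flowering curve. Species carrying a planted indicator
#' state have their flowering peak drawn inside the planted time group with
#' probability equal to the concentration strength. Flat-community plots have
#' no observations at skipped (mowing) times.
#'
#' @param config A [synthetic_config()].
#' @return A validated `flowering_study` with attribute `ground_truth`, a
#'   data frame listing the planted indicators (trait, state, planted group,
#'   expected direction).
#' @export
generate_study <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  times <- default_calendar()[seq_len(config$n_times), ]
  if (config$n_times > 12) {
    times <- data.frame(time_index = seq_len(config$n_times),
                        calendar_label = paste0("t", seq_len(config$n_times)))
  }
  skips <- do.call(rbind, lapply(names(config$skipped_times), function(cm) {
    data.frame(community = cm, time_index = as.integer(config$skipped_times[[cm]]))
  }))
  if (is.null(skips)) {
    skips <- data.frame(community = character(), time_index = integer())
  }

  obs_list <- list()
  trait_list <- list()
  plot_list <- list()
  for (cm in config$communities) {
    pool <- draw_species_pool(config, cm)
    trait_list[[cm]] <- pool$traits
    plot_ids <- sprintf("%s_p%02d", cm, seq_len(config$plots_per_community))
    plot_list[[cm]] <- data.frame(plot_id = plot_ids, community = cm,
                                  stringsAsFactors = FALSE)
    skip <- config$skipped_times[[cm]]
    ot <- setdiff(times$time_index, if (is.null(skip)) integer() else skip)
    for (p in plot_ids) {
      totals <- stats::rnbinom(length(pool$ids), mu = pool$nu,
                               size = config$dispersion)
      keep <- which(totals > 0)
      for (i in keep) {
        pr <- stats::dnorm(ot, mean = pool$mu[i], sd = pool$sigma[i])
        if (config$rebloom && cm == "flat" && !is.null(skip) &&
            length(skip) > 0) {
          post <- ot > max(skip)
          pr[post] <- pr[post] + 0.15 * max(pr)
        }
        if (sum(pr) <= 0) {
          pr <- as.numeric(ot == ot[which.min(abs(ot - pool$mu[i]))])
        }
        counts <- as.integer(stats::rmultinom(1, totals[i], pr / sum(pr)))
        nz <- which(counts > 0)
        if (length(nz) > 0) {
          obs_list[[length(obs_list) + 1L]] <- data.frame(
            plot_id = p, time_index = ot[nz], species_id = pool$ids[i],
            shoots_in_full_bloom = counts[nz], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  observations <- do.call(rbind, obs_list)
  traits <- do.call(rbind, trait_list)
  plots <- do.call(rbind, plot_list)
  rownames(traits) <- rownames(plots) <- NULL
  env <- generate_env(config, plots = plots, times = times, skips = skips,
                      reseed = FALSE)
  gt <- if (length(config$planted_indicators) > 0) {
    do.call(rbind, lapply(config$planted_indicators, function(pl) {
      data.frame(trait = pl$trait, state = pl$state,
                 planted_group = paste(sort(pl$group), collapse = ","),
                 strength = pl$strength, direction = "positive",
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(trait = character(), state = character(),
               planted_group = character(), strength = numeric(),
               direction = character())
  }
  study <- flowering_study(observations, traits, env, plots, times,
                           skips = skips)
  attr(study, "ground_truth") <- gt
  study
}

#' Generate synthetic environmental records
#'
#' @param config A [synthetic_config()].
#' @param plots,times,skips Optional pre-built metadata tables (used
#'   internally by [generate_study()]); derived from `config` when `NULL`.
#' @param reseed Seed the RNG from `config$seed` (default `TRUE`; internal
#'   callers pass `FALSE` to continue an existing stream).
#' @return Data frame of environmental records (one per plot x observed
#'   time).
#' @export
generate_env <- function(config, plots = NULL, times = NULL, skips = NULL,
                         reseed = TRUE) {
  validate_synthetic_config(config)
  if (reseed) set.seed(config$seed + 1L)
  if (is.null(times)) {
    times <- data.frame(time_index = seq_len(config$n_times))
  }
  if (is.null(plots)) {
    plots <- do.call(rbind, lapply(config$communities, function(cm) {
      data.frame(plot_id = sprintf("%s_p%02d", cm,
                                   seq_len(config$plots_per_community)),
                 community = cm, stringsAsFactors = FALSE)
    }))
  }
  ep <- config$env
  g <- config$n_times
  recs <- list()
  for (k in seq_len(nrow(plots))) {
    cm <- plots$community[k]
    skip <- config$skipped_times[[cm]]
    ot <- setdiff(times$time_index, if (is.null(skip)) integer() else skip)
    toff <- ep$temp_offsets[[cm]] %||% 0
    hoff <- ep$hum_offsets[[cm]] %||% 0
    cmax <- ep$canopy_max[[cm]] %||% 30
    tmean <- ep$temp_base + ep$temp_amplitude * sin(pi * (ot - 1) / (g - 1)) + toff
    hmean <- ep$hum_start + (ep$hum_end - ep$hum_start) * (ot - 1) / (g - 1) + hoff
    hmean[ot >= g - 1] <- hmean[ot >= g - 1] + ep$hum_autumn_recovery
    # logistic canopy growth; mown community restarts after the skip window
    grow <- function(t0, t) cmax / (1 + exp(-ep$canopy_rate * (t - t0 - 2.5)))
    cmean <- grow(0, ot)
    if (!is.null(skip) && length(skip) > 0 && cm == "flat") {
      post <- ot > max(skip)
      cmean[post] <- ep$mow_reset_height +
        (cmax / 3) / (1 + exp(-ep$canopy_rate * (ot[post] - max(skip) - 2.5)))
    }
    n <- length(ot)
    recs[[k]] <- data.frame(
      plot_id = plots$plot_id[k],
      time_index = ot,
      soil_temperature = tmean + stats::rnorm(n, 0, ep$noise_sd$temp),
      soil_relative_humidity = pmin(100, pmax(
        0, hmean + stats::rnorm(n, 0, ep$noise_sd$hum))),
      canopy_height = pmax(0, cmean + stats::rnorm(n, 0, ep$noise_sd$canopy)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Plant an indicator trait state into a base configuration
#'
#' Convenience wrapper: returns the generated study together with its ground
#' truth. Strength 0 reduces exactly to the base (null) generator.
#'
#' @param trait Trait name (must exist in the config vocabulary).
#' @param state State of that trait to plant.
#' @param time_group Integer vector of target observation times.
#' @param strength Concentration strength in [0, 1].
#' @param base_config A [synthetic_config()]; its seed is reused.
#' @return List with elements `study` and `ground_truth`.
#' @export
plant_indicator_fixture <- function(trait, state, time_group, strength,
                                    base_config = synthetic_config()) {
  cfg <- base_config
  cfg$planted_indicators <- c(
    cfg$planted_indicators,
    list(list(trait = trait, state = state, group = as.integer(time_group),
              strength = strength))
  )
  validate_synthetic_config(cfg)
  study <- generate_study(cfg)
  list(study = study, ground_truth = attr(study, "ground_truth"),
       config = cfg)
}

#' Generate a synthetic year of daily weather records
#'
#' A stand-in daily series for a sub-Mediterranean montane site: mean annual
#' temperature 10 degrees C with a seasonal sine cycle, and rainfall drawn
#' from seasonally weighted gamma pulses (spring/autumn wet, mid-summer
#' drought) rescaled so the annual total is exactly `annual_precip`.
#'
#' @param year Calendar year for the dates.
#' @param mean_temp Annual mean temperature (degrees C).
#' @param annual_precip Annual precipitation total (mm).
#' @param seed Integer seed.
#' @return Data frame with columns `date`, `temperature`, `precipitation`.
#' @export
generate_climate <- function(year = 2011, mean_temp = 10,
                             annual_precip = 1035, seed = 1L) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(doy)
  temp <- mean_temp + 9.5 * sin(2 * pi * (doy - 105) / 365.25) +
    stats::rnorm(n, 0, 2)
  temp <- temp - mean(temp) + mean_temp
  wet_weight <- 1 + 0.8 * cos(2 * pi * (doy - 310) / 365.25)
  wet_weight[doy >= 196 & doy <= 243] <- 0.15  # mid-Jul to end-Aug drought
  rain <- stats::rgamma(n, shape = 0.35, scale = 9) * wet_weight
  rain <- rain * annual_precip / sum(rain)
  data.frame(date = dates, temperature = temp, precipitation = rain)
}
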