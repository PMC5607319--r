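# Fixtures built in code: hand-sized studies and random small studies for
# property sweeps.

# one community, explicit counts; counts: named list species -> data.frame
# (plot, time, count). Every species gets the single trait "tr" with the
# given state.
tiny_study <- function(counts, states, n_plots = 2, times = 1:3,
                       community = "south") {
  plots <- data.frame(plot_id = paste0("p", seq_len(n_plots)),
                      community = community)
  obs <- do.call(rbind, lapply(names(counts), function(sp) {
    d <- counts[[sp]]
    data.frame(plot_id = d$plot, time_index = d$time, species_id = sp,
               shoots_in_full_bloom = d$count)
  }))
  traits <- data.frame(species_id = names(counts), trait = "tr",
                       state = states)
  tms <- data.frame(time_index = times, calendar_label = paste0("t", times))
  grid <- expand.grid(plot_id = plots$plot_id, time_index = times,
                      stringsAsFactors = FALSE)
  env <- data.frame(grid, soil_temperature = 10,
                    soil_relative_humidity = 50, canopy_height = 10)
  flowering_study(obs, traits, env, plots, tms)
}

# random small study: n_plots x n_times x n_species, uniform counts, each
# species one state of one trait (possibly shared)
random_small_study <- function(seed, n_plots = 3, n_times = 4,
                               n_species = 5, n_states = 2) {
  set.seed(seed)
  plots <- data.frame(plot_id = paste0("p", seq_len(n_plots)),
                      community = "south")
  sp <- paste0("s", seq_len(n_species))
  obs <- expand.grid(plot_id = plots$plot_id, time_index = seq_len(n_times),
                     species_id = sp, stringsAsFactors = FALSE)
  obs$shoots_in_full_bloom <- rpois(nrow(obs), 2)
  obs <- obs[obs$shoots_in_full_bloom > 0, ]
  traits <- data.frame(species_id = sp, trait = "tr",
                       state = sample(paste0("st", seq_len(n_states)),
                                      n_species, replace = TRUE))
  tms <- data.frame(time_index = seq_len(n_times),
                    calendar_label = paste0("t", seq_len(n_times)))
  grid <- expand.grid(plot_id = plots$plot_id,
                      time_index = seq_len(n_times),
                      stringsAsFactors = FALSE)
  env <- data.frame(grid,
                    soil_temperature = rnorm(nrow(grid), 15, 3),
                    soil_relative_humidity = runif(nrow(grid), 20, 80),
                    canopy_height = runif(nrow(grid), 5, 40))
  flowering_study(obs, traits, env, plots, tms)
}

# small synthetic config for fast end-to-end runs
small_config <- function(seed, plots = 6, species = 12, times = 6) {
  synthetic_config(
    seed = seed, plots_per_community = plots, n_times = times,
    species_pool_size = species,
    skipped_times = if (times >= 6) list(flat = c(4L, 5L)) else list()
  )
}
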