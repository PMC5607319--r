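test_that("default design is emulated: 105 plots, 12 times, 10 on flat", {
  st <- generate_study(synthetic_config(seed = 3, species_pool_size = 10))
  expect_equal(nrow(st$plots), 105L)
  expect_equal(sum(st$plots$community == "flat"), 35L)
  expect_equal(observed_times(st, "south"), 1:12)
  expect_equal(observed_times(st, "flat"), setdiff(1:12, c(8, 9)))
  flat_plots <- st$plots$plot_id[st$plots$community == "flat"]
  flat_obs <- st$observations[st$observations$plot_id %in% flat_plots, ]
  expect_equal(sort(unique(flat_obs$time_index)), setdiff(1:12, c(8, 9)))
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_study(small_config(5))
  b <- generate_study(small_config(5))
  expect_identical(a$observations, b$observations)
  expect_identical(a$env, b$env)
})

test_that("per species-plot, allocated counts sum to the seasonal total", {
  st <- generate_study(small_config(8))
  pr <- species_proportions(st)
  key <- paste(pr$plot_id, pr$species_id)
  sums <- tapply(pr$proportion, key, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # and raw counts agree with the recorded seasonal totals
  ck <- paste(st$observations$plot_id, st$observations$species_id)
  totals <- tapply(st$observations$shoots_in_full_bloom, ck, sum)
  expect_equal(as.numeric(totals[match(key, names(totals))]),
               pr$seasonal_total)
})

test_that("degenerate configs are rejected", {
  expect_error(synthetic_config(sigma_range = c(0, 1)),
               class = "tb_config_error")
  expect_error(synthetic_config(dispersion = -1), class = "tb_config_error")
  expect_error(synthetic_config(skipped_times = list(flat = 99L)),
               class = "tb_config_error")
  expect_error(
    plant_indicator_fixture("storage_organ", "no_such_state", 3, 0.5,
                            small_config(1)),
    class = "tb_config_error"
  )
})

test_that("environmental trajectories have the designed community contrasts", {
  t_south <- t_north <- h_flat <- h_south <- numeric(0)
  drop_mow <- numeric(0)
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, plots_per_community = 8,
                            species_pool_size = 4)
    env <- generate_env(cfg)
    plots <- data.frame(
      plot_id = unique(env$plot_id),
      community = sub("_p[0-9]+$", "", unique(env$plot_id))
    )
    sm <- env_seasonal_summary(env, plots)
    t_south <- c(t_south, mean(sm$temp_mean[sm$community == "south"]))
    t_north <- c(t_north, mean(sm$temp_mean[sm$community == "north"]))
    h_flat <- c(h_flat, mean(sm$hum_mean[sm$community == "flat"]))
    h_south <- c(h_south, mean(sm$hum_mean[sm$community == "south"]))
    flat <- sm[sm$community == "flat", ]
    pre <- flat$canopy_mean[flat$time_index == 7]   # last pre-mowing time
    post <- flat$canopy_mean[flat$time_index == 10] # first post-mowing time
    drop_mow <- c(drop_mow, pre - post)
  }
  expect_true(all(t_south > t_north))
  expect_true(all(h_flat > h_south))
  expect_true(all(drop_mow > 0))
})

test_that("zero noise makes trajectories identical across a community's plots", {
  cfg <- synthetic_config(seed = 2, plots_per_community = 4,
                          species_pool_size = 4,
                          env = default_env_params(
                            noise_sd = list(temp = 0, hum = 0, canopy = 0)))
  env <- generate_env(cfg)
  south <- env[grepl("^south", env$plot_id), ]
  byplot <- split(south[c("soil_temperature", "soil_relative_humidity",
                          "canopy_height")], south$plot_id)
  for (k in seq_along(byplot)[-1]) {
    expect_equal(byplot[[k]], byplot[[1]], ignore_attr = TRUE)
  }
})

test_that("strength 0 reduces the planted generator to the base generator", {
  base <- generate_study(small_config(31))
  fx <- plant_indicator_fixture("storage_organ", "bulb", c(2, 3), 0,
                                small_config(31))
  expect_identical(fx$study$observations, base$observations)
  expect_equal(fx$ground_truth$strength, 0)
})

test_that("strength 1 concentrates every carrier near the planted time", {
  fx <- plant_indicator_fixture("storage_organ", "tap_root", 3L, 1,
                                synthetic_config(seed = 17, n_times = 6,
                                                 plots_per_community = 6,
                                                 species_pool_size = 15,
                                                 skipped_times = list()))
  st <- fx$study
  carriers <- st$traits$species_id[st$traits$trait == "storage_organ" &
                                     st$traits$state == "tap_root"]
  obs <- st$observations[st$observations$species_id %in% carriers, ]
  expect_gt(nrow(obs), 0)
  # narrow synchronized curves centred on time 3: all shoots within one step
  expect_true(all(abs(obs$time_index - 3) <= 1))
  expect_gt(sum(obs$shoots_in_full_bloom[obs$time_index == 3]),
            0.8 * sum(obs$shoots_in_full_bloom))
})

test_that("synthetic climate hits the configured annual totals", {
  cl <- generate_climate(seed = 4)
  expect_equal(sum(cl$precipitation), 1035, tolerance = 1e-10)
  expect_equal(mean(cl$temperature), 10, tolerance = 1e-10)
  expect_equal(nrow(cl), 365L)
})

test_that("planted-indicator recovery is non-decreasing in strength", {
  planted <- c(2L, 3L)
  rate <- function(strength) {
    hits <- 0L
    for (seed in 1:12) {
      fx <- plant_indicator_fixture(
        "storage_organ", "tap_root", planted, strength,
        synthetic_config(seed = 600 + seed, plots_per_community = 20,
                         n_times = 8, species_pool_size = 30,
                         skipped_times = list(flat = 5L)))
      tm <- build_trait_matrix(fx$study)
      isa <- run_isa(tm, n_perm = 99, seed = seed,
                     states = data.frame(trait = "storage_organ",
                                         state = "tap_root"))
      ok <- any(vapply(seq_len(nrow(isa)), function(i) {
        grp <- as.integer(strsplit(isa$best_group[i], ",")[[1]])
        isa$retained[i] && length(intersect(grp, planted)) > 0
      }, TRUE))
      if (ok) hits <- hits + 1L
    }
    hits / 12
  }
  r <- vapply(c(0.2, 0.5, 0.9), rate, 0)
  expect_true(r[1] <= r[2] && r[2] <= r[3])
  expect_gt(r[3], 0.5)
})
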