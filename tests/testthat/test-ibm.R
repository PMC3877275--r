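# A minimal hand-built prepared survey with one station, used where the
# full generator is more than the test needs.
toy_prep <- function(bottom = 60, temp = 8, n_taxa_abund = 200) {
  nb <- min(floor(bottom), 100)
  traits <- data.frame(taxon = c("smallcop", "bigkrill"),
                       stage = "A", length_mm = c(1.5, 16),
                       width_mm = c(0.5, 2.5),
                       ind_biomass_g = c(2e-4, 3e-2),
                       ed_kj_g = c(3.6, 4.4), ed_single = FALSE)
  vp <- do.call(rbind, lapply(c("smallcop", "bigkrill"), function(tx) {
    do.call(rbind, lapply(c("day", "night"), function(period) {
      mu <- if (tx == "bigkrill" && period == "day") 50 else 15
      w <- stats::dnorm(0:99 + 0.5, mu, 12)
      data.frame(taxon = tx, period = period, depth_bin_top_m = 0:99,
                 fraction = w / sum(w))
    }))
  }))
  structure(list(
    stations = data.frame(station_id = "s1", lon = -165, lat = 57,
                          bottom_depth = bottom, domain = "middle",
                          regime = "warm"),
    temp_bins = data.frame(station_id = "s1", depth_m = 0:(nb - 1),
                           temp_c = temp),
    prey_traits = traits,
    main_prey = traits$taxon,
    prey_field = data.frame(station_id = "s1", taxon = traits$taxon,
                            abundance_n_per_m3 = c(n_taxa_abund, 2),
                            biomass_g_per_m3 = c(n_taxa_abund * 2e-4, 0.06)),
    vertical_profiles = vp,
    fish_energy = list(mean_fish_ed = 4.5, mean_weight = 2.2),
    regime = "warm"
  ), class = "survey_prep")
}

test_that("the light field cycles diurnally and decays with depth", {
  cfg <- ibm_config()
  expect_lt(irradiance(0, 0, cfg), 1)          # midnight below the switch
  expect_lt(irradiance(3.5, 0, cfg), 1)
  mid <- (cfg$sunrise + cfg$sunset) / 2
  expect_equal(irradiance(mid, 0, cfg), cfg$e0)
  zz <- irradiance(12, seq(0, 80, 5), cfg)
  expect_true(all(diff(zz) < 0))
  expect_error(irradiance(24), "hour")
})

test_that("prey profiles switch at the light threshold, inclusive for day", {
  expect_equal(active_profile(1.0), "day")
  expect_equal(active_profile(0.5), "night")
  expect_equal(active_profile(100), "day")
})

test_that("capture success is near 1 below 5% of fish length and declines to zero", {
  expect_equal(capture_success(3, 65), 1)      # ratio 0.046
  p <- capture_success(c(0.05, 0.10, 0.20) * 65, 65)
  expect_true(all(diff(p) <= 0))
  expect_equal(capture_success(0.3 * 65, 65), 0)
  # prey longer than the gape are uncapturable even at a modest ratio
  cfg <- ibm_config(gape_coef = 0.05)
  expect_equal(capture_success(4, 65, cfg), 0)
  expect_error(capture_success(-1, 65), "positive")
})

test_that("encounter rate is a clearance volume, linear in prey density", {
  expect_equal(encounter_rate(0, 0.1, 0.065), 0)
  n <- c(1, 5, 50)
  r <- encounter_rate(n, 0.1, 0.065)
  expect_equal(r / n, rep(r[1], 3))
  expect_equal(r[1], 0.5 * pi * 0.1^2 * 0.065)
  # visual range grows with light, saturating
  expect_gt(visual_range(2, 1500), visual_range(2, 15))
  expect_gt(visual_range(2, 15), visual_range(2, 1e-6))
  expect_equal(visual_range(2, 0), 2 / 1000)   # dark floor: one body length
  expect_error(encounter_rate(-1, 0.1, 0.05), "nonnegative")
})

test_that("feeding and digestion respect gut capacity and the Cmax cap", {
  cfg <- ibm_config()
  prm <- bioen_params()
  ind <- list(w = 2.5, length = 65, gut_mass = 0.1, gut_energy = 0.4)
  # empty environment: zero ingestion, geometric gut decay
  fd <- step_feed_digest(ind, 0, 0, 8, cfg, prm)
  expect_equal(fd$ingested_mass, 0)
  expect_equal(fd$ind$gut_mass, 0.1 * (1 - cfg$digestion_rate))
  fd2 <- step_feed_digest(fd$ind, 0, 0, 8, cfg, prm)
  expect_equal(fd2$ind$gut_mass, 0.1 * (1 - cfg$digestion_rate)^2)
  # saturating prey: gut never exceeds capacity
  sat <- step_feed_digest(ind, 10, 40, 8, cfg, prm)
  expect_lte(sat$ind$gut_mass, cfg$gut_capacity_frac * 2.5 + 1e-12)
  # digested supply never exceeds the hourly Cmax allowance
  full <- list(w = 2.5, length = 65, gut_mass = 0.15, gut_energy = 0.6)
  s <- step_feed_digest(full, 10, 40, 8, cfg, prm)
  expect_lte(s$supply_mass, cmax(2.5, 8, prm) * 2.5 / 24 + 1e-12)
  expect_gt(s$overflow_energy, 0)
})

test_that("the migration surcharge is 10% of standard metabolism at full displacement", {
  cfg <- ibm_config()
  prm <- bioen_params()
  ind <- list(w = 2.5, length = 65, gut_mass = 0, gut_energy = 0)
  smr_h <- respiration(2.5, 8, prm, active = FALSE) * prm$o2cal / 1000 /
    24 * 2.5
  still <- step_metabolism_growth(ind, 0.02, 8, dz = 0, fish_ed = 4.5,
                                  cfg, prm)
  expect_equal(still$mig_energy, 0)
  fullm <- step_metabolism_growth(ind, 0.02, 8, dz = cfg$max_dz,
                                  fish_ed = 4.5, cfg, prm)
  expect_equal(fullm$mig_energy, 0.1 * smr_h)
  half <- step_metabolism_growth(ind, 0.02, 8, dz = -cfg$max_dz / 2,
                                 fish_ed = 4.5, cfg, prm)
  expect_equal(half$mig_energy, 0.05 * smr_h)
})

test_that("the behaviour rule trades depth against energy", {
  # prey only at the surface and nothing meets the requirement: move up
  net <- c(-0.001, rep(-0.01, 59))
  ing <- c(0.02, rep(0, 59))
  expect_lt(behavior_step(40, net, ing, max_dz = 60), 40)
  expect_equal(behavior_step(40, net, ing, max_dz = 60), 0)
  # abundant prey at all depths: go as deep as reachable
  net_rich <- rep(0.05, 60)
  expect_equal(behavior_step(20, net_rich, rep(1, 60), max_dz = 30), 50)
  expect_equal(behavior_step(50, net_rich, rep(1, 60), max_dz = 30), 59)
  # never leaves the column
  expect_lte(behavior_step(59, net_rich, rep(1, 60), max_dz = 30), 59)
})

test_that("a station simulation is seeded, bounded, and balances its books", {
  prep <- toy_prep()
  env <- build_ibm_environment(prep, "s1")
  r1 <- simulate_station(env, n_fish = 8, hours = 72, seed = 5,
                         fish_ed = 4.5)
  r2 <- simulate_station(env, n_fish = 8, hours = 72, seed = 5,
                         fish_ed = 4.5)
  expect_identical(r1$growth, r2$growth)
  expect_identical(r1$mean_depth, r2$mean_depth)
  r3 <- simulate_station(env, n_fish = 8, hours = 72, seed = 6,
                         fish_ed = 4.5)
  expect_false(identical(r1$growth, r3$growth))
  expect_gte(r1$mean_depth, 0)
  expect_lte(r1$mean_depth, env$n_bins)
  # energy ledger: ingested = gut change + digested; digested splits into
  # capped supply + overflow; supply splits into waste + net
  led <- r1$ledger
  expect_equal(led[["ingested"]] - led[["gut_delta"]],
               led[["supplied"]] + led[["overflow"]], tolerance = 1e-9)
  expect_equal(led[["supplied"]], led[["waste"]] + led[["net"]],
               tolerance = 1e-9)
})

test_that("fish starve in an empty ocean", {
  prep <- toy_prep()
  prep$prey_field$abundance_n_per_m3 <- 0
  prep$prey_field$biomass_g_per_m3 <- 0
  env <- build_ibm_environment(prep, "s1")
  r <- simulate_station(env, n_fish = 6, hours = 48, seed = 1,
                        fish_ed = 4.5)
  expect_lt(r$growth, 0)
})

test_that("IBM growth never exceeds the bioenergetics ceiling at matched conditions", {
  prep <- fixture_prep("warm")
  ids <- prep$stations$station_id[1:3]
  res <- ibm_by_station(prep, n_fish = 15, hours = 72, seed = 11,
                        stations = ids)
  max_ed <- max(prep$prey_traits$ed_kj_g)
  for (i in seq_along(ids)) {
    temps <- prep$temp_bins$temp_c[prep$temp_bins$station_id == ids[i]]
    # ceiling: eta = 1 growth at the most favourable temperature in the
    # column, the richest prey, and the lightest possible fish
    ceiling <- max(growth(2.5 * 0.7, temps, max_ed,
                          prep$fish_energy$mean_fish_ed, 1)$growth)
    expect_lte(res$growth[i], ceiling + 1e-9)
  }
})

test_that("a fully mixed single-bin column makes vertical structure irrelevant", {
  prep <- toy_prep(bottom = 1.9)
  env_base <- build_ibm_environment(prep, "s1")
  env_unif <- build_ibm_environment(prep, "s1", uniform_prey = TRUE)
  expect_equal(env_base$n_bins, 1)
  expect_equal(env_base$n_day, env_unif$n_day)
  r_base <- simulate_station(env_base, n_fish = 6, hours = 48, seed = 3,
                             fish_ed = 4.5)
  r_unif <- simulate_station(env_unif, n_fish = 6, hours = 48, seed = 3,
                             fish_ed = 4.5)
  expect_equal(r_base$growth, r_unif$growth)
  expect_equal(r_base$mean_depth, r_unif$mean_depth)
})

test_that("station runs respect depth bounds across the survey", {
  prep <- fixture_prep("cold")
  ids <- prep$stations$station_id[1:2]
  res <- ibm_by_station(prep, n_fish = 10, hours = 48, seed = 2,
                        stations = ids)
  bd <- prep$stations$bottom_depth[match(ids, prep$stations$station_id)]
  expect_true(all(res$mean_depth >= 0))
  expect_true(all(res$mean_depth <= pmin(bd, 100)))
})
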