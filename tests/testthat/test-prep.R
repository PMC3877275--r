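make_obs <- function(n, d, h, tow = "surface", id = "a") {
  data.frame(station_id = id, tow_type = tow, n_caught = n,
             trawl_distance_m = d, trawl_spread_m = h,
             stringsAsFactors = FALSE)
}

test_that("CPUE is catch over swept area, surface tows only", {
  expect_equal(compute_cpue(make_obs(0, 1500, 50))$cpue, 0)
  expect_equal(compute_cpue(make_obs(50, 1000, 50))$cpue, 0.001)
  expect_equal(compute_cpue(make_obs(50, 2000, 50))$cpue,
               compute_cpue(make_obs(50, 1000, 50))$cpue / 2)
  expect_warning(out <- compute_cpue(rbind(make_obs(10, 1000, 50),
                                           make_obs(99, 1000, 50, "midwater",
                                                    "b"))),
                 "non-surface")
  expect_equal(nrow(out), 1)
  expect_error(compute_cpue(make_obs(5, 0, 50)), "positive")
  expect_error(compute_cpue(make_obs(5, 1000, -1)), "positive")
})

test_that("diet composition is CPUE-weighted across stations", {
  diet <- data.frame(
    station_id = rep(c("a", "b"), each = 2),
    taxon = rep(c("x", "y"), 2),
    percent_volume = c(80, 20, 40, 60)
  )
  one <- weighted_diet_composition(diet[diet$station_id == "a", ],
                                   data.frame(station_id = "a", cpue = 0.3))
  expect_equal(one$percent_volume[one$taxon == "x"], 80)
  eq <- weighted_diet_composition(diet, data.frame(station_id = c("a", "b"),
                                                   cpue = c(2, 2)))
  expect_equal(eq$percent_volume[eq$taxon == "x"], 60)
  # 3:1 weighting against a hand computation
  w31 <- weighted_diet_composition(diet, data.frame(station_id = c("a", "b"),
                                                    cpue = c(3, 1)))
  expect_equal(w31$percent_volume[w31$taxon == "x"], 0.75 * 80 + 0.25 * 40)
  expect_equal(sum(w31$percent_volume), 100)
  expect_warning(
    z <- weighted_diet_composition(diet,
                                   data.frame(station_id = c("a", "b"),
                                              cpue = c(0, 0))),
    "unweighted")
  expect_equal(z$percent_volume[z$taxon == "x"], 60)
  expect_error(weighted_diet_composition(
    data.frame(station_id = "a", taxon = c("x", "y"),
               percent_volume = c(80, 30)),
    data.frame(station_id = "a", cpue = 1)), "100")
})

test_that("main-prey selection reproduces the published cumulative diet columns", {
  sel_w <- select_main_prey(c(diet_warm_year, minor_taxa))
  expect_equal(sel_w$taxon, names(diet_warm_year))
  expect_equal(sel_w$cumulative_display,
               c(26.3, 52.4, 64.2, 73.2, 81.7, 86.3, 89.7, 91.4))
  expect_equal(sel_w$cumulative_display[sel_w$taxon == "Calanus marshallae"],
               91.4)
  sel_c <- select_main_prey(c(diet_cold_year, minor_taxa))
  expect_equal(sel_c$taxon, names(diet_cold_year))
  expect_equal(sel_c$cumulative_display,
               c(35.5, 62.5, 76.4, 81.2, 84.4, 87.5, 90.5, 93.4))
  expect_equal(sel_c$cumulative_display[sel_c$taxon == "Eucalanus bungii"],
               93.4)
})

test_that("main-prey selection handles edge cases and breaks ties alphabetically", {
  single <- select_main_prey(c(only = 100))
  expect_equal(single$taxon, "only")
  expect_equal(single$cumulative_display, 100.0)
  expect_equal(nrow(select_main_prey(numeric())), 0)
  tied <- select_main_prey(c(b = 50, a = 50))
  expect_equal(tied$taxon, c("a", "b"))
  # a taxon >= 2% past the 90% crossing is retained; below 2% is not
  sel <- select_main_prey(c(a = 60, b = 33, c = 2.5, d = 1.9))
  expect_equal(sel$taxon, c("a", "b", "c"))
})

test_that("the modelling set is the union of regime selections minus exclusions", {
  u <- main_prey_union(select_main_prey(c(diet_warm_year, minor_taxa)),
                       select_main_prey(c(diet_cold_year, minor_taxa)),
                       exclude = "Neocalanus plumchrus")
  expect_true(all(c("Limacina helicina", "Calanus marshallae",
                    "Thysanoessa raschii") %in% u))
  expect_false("Neocalanus plumchrus" %in% u)
})

test_that("the ED-lipid regression is ordinary least squares with guards", {
  # collinear input triggers base R's perfect-fit note; the fit itself is fine
  perfect <- suppressWarnings(
    fit_ed_lipid_regression(c(5, 10, 20, 40), 19.3 + 0.41 * c(5, 10, 20, 40))
  )
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$alpha, 19.3)
  expect_equal(perfect$beta, 0.41)
  expect_error(fit_ed_lipid_regression(c(1, 2), c(1, 2)), "3 samples")
  expect_error(fit_ed_lipid_regression(c(5, 5, 5), c(1, 2, 3)), "variance")
})

test_that("ED predictions are linear in lipid with the printed coefficients", {
  reg <- list(alpha = 19.3, beta = 0.41)
  expect_equal(predict_ed_from_lipid(0, reg), 19.3)
  expect_equal(predict_ed_from_lipid(10, reg), 23.4)
  ll <- c(4, 9, 17)
  expect_equal(predict_ed_from_lipid(2 * ll, reg) -
                 predict_ed_from_lipid(ll, reg), 0.41 * ll)
  expect_error(predict_ed_from_lipid(-1, reg), ">= 0")
})

test_that("station prey energy is the biomass-weighted mean of taxon EDs", {
  traits <- data.frame(taxon = c("x", "y", "z"), ed_kj_g = c(2, 4, 6))
  one <- station_prey_energy(
    data.frame(station_id = "a", taxon = "y", biomass_g_per_m3 = 0.3),
    traits)
  expect_equal(one$prey_ed, 4)
  two <- station_prey_energy(
    data.frame(station_id = "a", taxon = c("x", "y"),
               biomass_g_per_m3 = c(0.2, 0.2)), traits)
  expect_equal(two$prey_ed, 3)
  set.seed(11)
  b <- runif(3)
  mix <- station_prey_energy(
    data.frame(station_id = "a", taxon = c("x", "y", "z"),
               biomass_g_per_m3 = b), traits)
  expect_equal(mix$prey_ed, sum(b / sum(b) * c(2, 4, 6)), tolerance = 1e-12)
  expect_gte(mix$prey_ed, 2)
  expect_lte(mix$prey_ed, 6)
  expect_warning(zz <- station_prey_energy(
    data.frame(station_id = "a", taxon = "x", biomass_g_per_m3 = 0),
    traits), "flagged")
  expect_true(is.na(zz$prey_ed))
})

test_that("mean individual biomass is subsample mass over subsample count", {
  expect_equal(mean_individual_biomass(rep(0.005, 10), 10), 0.005)
  expect_equal(mean_individual_biomass(0.013, 1), 0.013)
  w <- c(0.01, 0.002, 0.03)
  expect_equal(mean_individual_biomass(w, 3),
               mean_individual_biomass(rev(w), 3))
  expect_error(mean_individual_biomass(w, 0), "> 0")
})

test_that("vertical profiles spread strata uniformly, average tows, and normalize", {
  s1 <- data.frame(tow_id = "t1", taxon = "x", period = "day",
                   depth_top_m = 0, depth_bottom_m = 20,
                   abundance_n_per_m3 = 8)
  p1 <- suppressWarnings(build_vertical_profiles(s1, column_depth = 100))
  day1 <- p1[p1$period == "day", ]
  expect_equal(day1$fraction[day1$depth_bin_top_m < 20], rep(0.05, 20))
  expect_equal(sum(day1$fraction[day1$depth_bin_top_m >= 20]), 0)
  # two tows average as the mean of the individual tow profiles
  s2 <- rbind(s1, data.frame(tow_id = "t2", taxon = "x", period = "day",
                             depth_top_m = c(0, 20),
                             depth_bottom_m = c(20, 40),
                             abundance_n_per_m3 = c(2, 2)))
  p2 <- suppressWarnings(build_vertical_profiles(s2, column_depth = 100))
  day2 <- p2[p2$period == "day", ]
  dens <- c(rep((8 + 2) / 2, 20), rep(1, 20), rep(0, 60))
  expect_equal(day2$fraction, dens / sum(dens))
  for (pp in split(p2, p2$period)) {
    expect_equal(sum(pp$fraction), 1, tolerance = 1e-9)
  }
})

test_that("vertical-profile fallbacks substitute donors, genus means, or uniform", {
  s <- data.frame(tow_id = c("t1", "t2", "t3"),
                  taxon = c("Oiko sp.", "Oiko sp.", "Thys alpha"),
                  period = c("night", "day", "day"),
                  depth_top_m = c(0, 0, 40), depth_bottom_m = c(10, 30, 60),
                  abundance_n_per_m3 = 5)
  # absent day tows for a taxon borrow the designated donor profile
  s_no_day <- s[s$tow_id != "t2", ]
  fb <- list("Oiko sp." = list(day = list(taxon = "Oiko sp.",
                                          period = "night")))
  p <- build_vertical_profiles(s_no_day, column_depth = 100, fallbacks = fb,
                               taxa = "Oiko sp.")
  expect_equal(p$fraction[p$period == "day"],
               p$fraction[p$period == "night"])
  # rarely caught congener takes the genus-average profile
  s_genus <- rbind(s, data.frame(tow_id = "t4", taxon = "Thys beta",
                                 period = "day", depth_top_m = 0,
                                 depth_bottom_m = 20,
                                 abundance_n_per_m3 = 1))
  pg <- suppressWarnings(build_vertical_profiles(
    s_genus, column_depth = 100, taxa = c("Thys alpha", "Thys beta"),
    genus_average = "Thys beta"))
  a_day <- pg$fraction[pg$taxon == "Thys alpha" & pg$period == "day"]
  b_day <- pg$fraction[pg$taxon == "Thys beta" & pg$period == "day"]
  b_raw <- c(rep(0.05, 20), rep(0, 80))  # beta's own sparse day profile
  expect_equal(b_day, (a_day + b_raw) / 2)
  # a taxon absent everywhere warns for each period and falls back to uniform
  expect_warning(
    expect_warning(pu <- build_vertical_profiles(s, column_depth = 50,
                                                 taxa = "ghost"),
                   "uniform"),
    "uniform")
  expect_equal(pu$fraction, rep(1 / 50, 100))
})

test_that("temperature preparation averages, interpolates, and fills from donors", {
  st <- data.frame(station_id = c("a", "b", "c"),
                   lon = c(-165, -165.01, -170), lat = c(57, 57.01, 60),
                   bottom_depth = c(60, 62, 58))
  tp <- data.frame(station_id = "a", depth_m = c(0, 59), temp_c = c(8, 8))
  out <- suppressWarnings(prep_temperature(tp, st[1, ]))
  expect_equal(out$upper30$upper30_temp, 8)
  # linear 10 -> 4 over the upper 30 m averages to 7 exactly
  lin <- data.frame(station_id = "a", depth_m = c(0, 30, 59),
                    temp_c = c(10, 4, 4))
  expect_equal(prep_temperature(lin, st[1, ])$upper30$upper30_temp, 7)
  # interpolation: 6 at 0 m and 4 at 10 m give 5 at 5 m
  gap <- data.frame(station_id = "a", depth_m = c(0, 10), temp_c = c(6, 4))
  bins <- prep_temperature(gap, st[1, ])$bins
  expect_equal(bins$temp_c[bins$depth_m == 5], 5)
  # a station with no profile is filled from the nearest similar-depth donor
  filled <- suppressWarnings(prep_temperature(lin, st[1:2, ]))
  expect_true("b" %in% filled$bins$station_id)
  expect_equal(filled$upper30$upper30_temp[filled$upper30$station_id == "b"],
               7)
  # no similar-depth donor -> excluded with a warning
  st_far <- data.frame(station_id = c("a", "d"), lon = c(-165, -166),
                       lat = c(57, 57), bottom_depth = c(60, 180))
  expect_warning(ex <- prep_temperature(lin, st_far), "excluded")
  expect_false("d" %in% ex$upper30$station_id)
  expect_error(prep_temperature(lin[0, ], st), "no temperature")
})

test_that("survey mean fish energy density is weighted by CPUE times fish processed", {
  obs <- data.frame(station_id = c("a", "b"), tow_type = "surface",
                    n_caught = c(100, 50), trawl_distance_m = 1000,
                    trawl_spread_m = 50, n_processed = c(4, 2),
                    mean_weight_g = c(2, 3),
                    mean_fish_ed_kj_g = c(4, 5))
  one <- fish_energy_summary(obs[1, ])
  expect_equal(one$mean_fish_ed, 4)
  # equal weights -> midpoint
  obs_eq <- obs
  obs_eq$n_caught <- 100
  obs_eq$n_processed <- 4
  expect_equal(fish_energy_summary(obs_eq)$mean_fish_ed, 4.5)
  # brute-force weighted mean
  cpue <- compute_cpue(obs)$cpue
  w <- cpue * obs$n_processed
  expect_equal(fish_energy_summary(obs)$mean_fish_ed,
               sum(w * obs$mean_fish_ed_kj_g) / sum(w))
  obs0 <- obs
  obs0$n_processed <- 0
  expect_error(fish_energy_summary(obs0), "processed")
})
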