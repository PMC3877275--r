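# Synthetic warm/cold shelf survey scenarios.
#
# The generator emulates the statistical structure of late-summer shelf
# surveys under two climate regimes: a "warm" year (warmer upper 30 m,
# small-copepod-dominated prey, lower mean prey energy density, broad
# middle/outer-domain fish distribution) and a "cold" year (the reverse, with
# an extensive cold pool of bottom water < 2 deg C and fish concentrated over
# the southern shelf). All distributional choices are package conventions,
# documented in the methods vignette; the regime contrasts themselves are the
# fixed study conditions.

.gs_taxa <- function() {
  # Synthetic prey trait table mirroring the structure of a stagewise
  # field trait table: one row per main prey taxon with length (mm), width
  # (mm), individual wet biomass (g) and wet-weight energy density (kJ/g) by
  # regime. Taxa flagged `ed_single` carry one shared ED estimate.
  df <- data.frame(
    taxon = c("Limacina helicina", "Pseudocalanus sp.", "Oikopleura sp.",
              "Centropages abdominalis", "Acartia clausi",
              "Calanus marshallae", "Neocalanus cristatus",
              "Neocalanus plumchrus", "Eucalanus bungii",
              "Thysanoessa raschii", "Thysanoessa inermis",
              "Thysanoessa inspinata"),
    stage = c("J", "C", "A", "A", "A", "C5", "C5", "C5", "A", "J", "J", "J"),
    length_mm = c(2.0, 1.0, 2.0, 1.1, 0.9, 3.5, 7.0, 4.5, 5.5, 15, 18, 14),
    width_mm = c(1.8, 0.35, 0.5, 0.4, 0.35, 1.0, 1.8, 1.2, 1.4,
                 2.5, 3.0, 2.3),
    ind_biomass_g = c(2e-3, 1.5e-4, 5e-4, 8e-5, 5e-5, 8e-4, 6e-3, 3e-3,
                      4e-3, 3e-2, 4.5e-2, 2.5e-2),
    ed_warm = c(4.6, 3.4, 1.8, 3.0, 2.8, 4.8, 5.2, 5.0, 4.0, 4.2, 4.4, 4.3),
    ed_cold = c(4.6, 3.8, 1.8, 3.0, 2.8, 5.8, 6.2, 6.0, 4.8, 4.6, 4.8, 4.3),
    ed_single = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  df
}

# Small copepod taxa (warm-regime indicators).
.gs_small_copepods <- c("Pseudocalanus sp.", "Acartia clausi",
                        "Centropages abdominalis")

.gs_composition <- function(regime) {
  w <- if (regime == "warm") {
    c("Limacina helicina" = 0.26, "Pseudocalanus sp." = 0.26,
      "Oikopleura sp." = 0.12, "Centropages abdominalis" = 0.09,
      "Thysanoessa raschii" = 0.085, "Acartia clausi" = 0.034,
      "Calanus marshallae" = 0.017, "Neocalanus cristatus" = 0.02,
      "Neocalanus plumchrus" = 0.03, "Thysanoessa inermis" = 0.05,
      "Eucalanus bungii" = 0.02, "Thysanoessa inspinata" = 0.014)
  } else {
    c("Limacina helicina" = 0.35, "Thysanoessa inermis" = 0.27,
      "Calanus marshallae" = 0.14, "Neocalanus cristatus" = 0.05,
      "Thysanoessa inspinata" = 0.03, "Thysanoessa raschii" = 0.03,
      "Eucalanus bungii" = 0.03, "Pseudocalanus sp." = 0.05,
      "Acartia clausi" = 0.01, "Centropages abdominalis" = 0.02,
      "Oikopleura sp." = 0.02, "Neocalanus plumchrus" = 0)
  }
  w[.gs_taxa()$taxon]
}

#' Prey trait table for a survey regime
#'
#' Returns the synthetic per-taxon trait table (length, width, individual wet
#' biomass, wet-weight energy density) for the main prey taxa of juvenile
#' pollock under the given regime. Taxa flagged `ed_single` lack
#' regime-specific energy estimates and carry one shared value in both
#' regimes; for those taxa only abundance and biomass differences contribute
#' to regime contrasts in available prey energy.
#'
#' @param regime `"warm"` or `"cold"`.
#' @return A data frame with columns `taxon`, `stage`, `length_mm`,
#'   `width_mm`, `ind_biomass_g`, `ed_kj_g`, `ed_single`.
#' @export
make_prey_traits <- function(regime = c("warm", "cold")) {
  regime <- match.arg(regime)
  df <- .gs_taxa()
  df$ed_kj_g <- if (regime == "warm") df$ed_warm else df$ed_cold
  df[, c("taxon", "stage", "length_mm", "width_mm", "ind_biomass_g",
         "ed_kj_g", "ed_single")]
}

#' Day/night vertical distribution profiles for prey taxa
#'
#' Builds taxon-specific day and night vertical distributions over 1-m depth
#' bins (0-100 m), emulating depth-stratified net data: strong diel vertical
#' migrators (euphausiids, large calanoids) sit deeper by day than by night,
#' small copepods migrate weakly, and Centropages is uniform throughout the
#' water column in both periods. Cold-regime profiles sit slightly deeper.
#' Fractions within each taxon x period sum to 1.
#'
#' @param regime `"warm"` or `"cold"`.
#' @param taxa Taxa to include; defaults to the full trait-table set.
#' @return A data frame with columns `taxon`, `period` (`"day"`/`"night"`),
#'   `depth_bin_top_m` (0..99) and `fraction`.
#' @export
make_vertical_profiles <- function(regime = c("warm", "cold"),
                                   taxa = make_prey_traits(regime)$taxon) {
  regime <- match.arg(regime)
  centers <- data.frame(
    taxon = .gs_taxa()$taxon,
    day_mean = c(25, 30, 15, NA, 15, 40, 60, 50, 55, 70, 75, 70),
    night_mean = c(12, 20, 12, NA, 10, 15, 30, 25, 30, 20, 25, 22),
    sd = c(10, 15, 8, NA, 8, 15, 20, 18, 18, 15, 15, 15),
    stringsAsFactors = FALSE
  )
  shift <- if (regime == "cold") 5 else 0
  z <- 0:99
  rows <- lapply(taxa, function(tx) {
    ci <- centers[centers$taxon == tx, ]
    if (nrow(ci) == 0) ci <- data.frame(day_mean = NA, night_mean = NA,
                                        sd = NA)
    per_period <- lapply(c("day", "night"), function(period) {
      if (is.na(ci$sd)) {                     # uniform: no net data, mixed
        frac <- rep(1 / length(z), length(z))
      } else {
        mu <- (if (period == "day") ci$day_mean else ci$night_mean) + shift
        w <- stats::dnorm(z + 0.5, mean = mu, sd = ci$sd)
        frac <- w / sum(w)
      }
      data.frame(taxon = tx, period = period, depth_bin_top_m = z,
                 fraction = frac, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_period)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scenario configuration for the synthetic survey generator
#'
#' Collects every knob of the generator: regime, station count, seed, grid
#' extent, regime target for the mean upper-30-m temperature, cold-pool
#' fraction (proportion of stations with bottom water < 2 deg C), prey
#' composition weights, total prey biomass scale, fish CPUE intensity and
#' distribution-centre parameters, and trawl geometry.
#'
#' Defaults encode the two study regimes: warm targets a mean upper-30-m
#' temperature of 8.8 deg C with a limited cold pool and a broad
#' middle/outer-shelf fish distribution; cold targets 7.6 deg C with an
#' extensive cold pool and fish concentrated over the southern shelf.
#'
#' @param regime `"warm"` or `"cold"`.
#' @param n_stations Number of survey stations (>= 1).
#' @param seed Integer seed; a fixed seed yields a byte-identical bundle.
#' @param lon_range,lat_range Grid extent, degrees.
#' @param target_upper30 Regime mean upper-30-m temperature, deg C.
#' @param cold_pool_frac Proportion of stations with bottom water < 2 deg C.
#' @param composition Named prey biomass-composition weights summing to 1.
#' @param total_biomass Regime-mean total prey biomass, g m^-3.
#' @param cpue_scale Peak expected CPUE, fish m^-2.
#' @param cpue_center Centre (lon, lat) of the fish distribution.
#' @param cpue_width Gaussian width of the fish distribution, degrees.
#' @param trawl_spread Horizontal trawl spread, m (survey constant).
#' @param temp_sd Between-station SD of mixed-layer temperature, deg C.
#' @param thermocline_depth,thermocline_width Logistic thermocline centre
#'   and width, m, for stratified (middle/outer) stations; inner-domain
#'   stations are fully mixed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(regime = c("warm", "cold"),
                            n_stations = 30,
                            seed = 1,
                            lon_range = c(-175, -160),
                            lat_range = c(54.5, 62),
                            target_upper30 = NULL,
                            cold_pool_frac = NULL,
                            composition = NULL,
                            total_biomass = NULL,
                            cpue_scale = NULL,
                            cpue_center = NULL,
                            cpue_width = NULL,
                            trawl_spread = 50,
                            temp_sd = 1.5,
                            thermocline_depth = 35,
                            thermocline_width = 3) {
  regime <- match.arg(regime)
  warm <- regime == "warm"
  cfg <- list(
    regime = regime,
    n_stations = n_stations,
    seed = seed,
    lon_range = lon_range,
    lat_range = lat_range,
    target_upper30 = target_upper30 %||% if (warm) 8.8 else 7.6,
    bottom_temp_mean = if (warm) 4.5 else 2.9,
    cold_pool_frac = cold_pool_frac %||% if (warm) 0.15 else 0.55,
    composition = composition %||% .gs_composition(regime),
    total_biomass = total_biomass %||% if (warm) 0.06 else 0.12,
    cpue_scale = cpue_scale %||% if (warm) 0.08 else 0.01,
    cpue_center = cpue_center %||% if (warm) c(-168, 59) else c(-165.5, 56.8),
    cpue_width = cpue_width %||% if (warm) 3.5 else 1.8,
    trawl_spread = trawl_spread,
    temp_sd = temp_sd,
    thermocline_depth = thermocline_depth,
    thermocline_width = thermocline_width
  )
  if (!is.numeric(cfg$n_stations) || cfg$n_stations < 1) {
    stop("n_stations must be >= 1", call. = FALSE)
  }
  if (cfg$cold_pool_frac < 0 || cfg$cold_pool_frac > 1) {
    stop("cold_pool_frac must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$composition) - 1) > 1e-6) {
    stop("prey composition weights must sum to 1", call. = FALSE)
  }
  if (any(cfg$composition < 0)) {
    stop("prey composition weights must be nonnegative", call. = FALSE)
  }
  if (cfg$trawl_spread <= 0) stop("trawl_spread must be > 0", call. = FALSE)
  structure(cfg, class = "scenario_config")
}

#' Generate a synthetic survey bundle
#'
#' Draws a complete station set for one regime: station grid with bottom
#' depths and shelf-domain labels, 1-m temperature profiles (two-layer with a
#' logistic thermocline at stratified stations, fully mixed inner-domain
#' stations, cold-pool bottom water at the configured fraction of stations),
#' per-taxon prey abundance/biomass fields with an inshore-offshore gradient
#' and log-normal station variability, the prey trait table, day/night
#' vertical profiles, fish trawl observations (thinned Gaussian CPUE
#' intensity centred per regime, zero-catch stations included) and station
#' diet records drawn proportional to local prey biomass.
#'
#' Mixed-layer temperatures are calibrated (an exact linear shift) so the
#' bundle mean upper-30-m temperature equals the regime target.
#'
#' @param config A [scenario_config()].
#' @return An object of class `survey_bundle`: a list of data frames
#'   (`stations`, `temperature`, `prey_field`, `prey_traits`,
#'   `vertical_profiles`, `fish_obs`, `diet`) plus the generating config.
#' @examples
#' b <- make_scenario(scenario_config("warm", n_stations = 10, seed = 1))
#' mean(prep_temperature(b$temperature, b$stations)$upper30$upper30_temp)
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    n <- config$n_stations
    stations <- .gs_make_stations(config, n)
    temperature <- .gs_make_temperature(config, stations)
    traits <- make_prey_traits(config$regime)
    prey_field <- .gs_make_prey_field(config, stations, traits)
    profiles <- make_vertical_profiles(config$regime, traits$taxon)
    fish_obs <- .gs_make_fish_obs(config, stations)
    diet <- .gs_make_diet(config, stations, prey_field, fish_obs)
    bundle <- list(stations = stations, temperature = temperature,
                   prey_field = prey_field, prey_traits = traits,
                   vertical_profiles = profiles, fish_obs = fish_obs,
                   diet = diet, config = config)
    class(bundle) <- "survey_bundle"
    bundle
  })
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat(sprintf("Synthetic survey bundle: %s regime, %d stations (seed %d)\n",
              x$config$regime, nrow(x$stations), x$config$seed))
  cat(sprintf("  domains: %s\n",
              paste(names(table(x$stations$domain)),
                    table(x$stations$domain), collapse = ", ")))
  cat(sprintf("  prey taxa: %d; diet stations: %d; positive-catch: %d\n",
              length(unique(x$prey_field$taxon)),
              length(unique(x$diet$station_id)),
              sum(x$fish_obs$n_caught > 0)))
  invisible(x)
}

.gs_make_stations <- function(config, n) {
  lon <- stats::runif(n, config$lon_range[1], config$lon_range[2])
  lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
  # offshore coordinate: deeper toward the west/northwest of the grid
  u_lon <- (config$lon_range[2] - lon) / diff(config$lon_range)
  u_lat <- (lat - config$lat_range[1]) / diff(config$lat_range)
  u <- pmin(pmax(0.7 * u_lon + 0.3 * u_lat + stats::rnorm(n, 0, 0.08), 0), 1)
  depth <- pmin(pmax(15 + 185 * u^1.3, 15), 200)
  data.frame(
    station_id = sprintf("st%03d", seq_len(n)),
    lon = lon, lat = lat,
    bottom_depth = depth,
    domain = shelf_domain(depth),
    regime = config$regime,
    stringsAsFactors = FALSE
  )
}

.gs_make_temperature <- function(config, stations) {
  n <- nrow(stations)
  zc <- config$thermocline_depth
  zw <- config$thermocline_width
  stratified <- stations$domain != "inner"
  # nearshore stations run warmer at the surface
  u <- 1 - pmin(stations$bottom_depth / 200, 1)
  t_mix <- config$target_upper30 + stats::rnorm(n, 0, config$temp_sd) +
    1.2 * (u - mean(u))
  t_bot <- pmax(stats::rnorm(n, config$bottom_temp_mean, 0.8), 2.2)
  # cold pool: bottom water < 2 degC at the configured fraction of stations
  n_pool <- min(round(config$cold_pool_frac * n), sum(stratified))
  if (n_pool > 0) {
    pool_idx <- sample(which(stratified), n_pool)
    t_bot[pool_idx] <- stats::runif(n_pool, 0.3, 1.8)
  }
  # calibrate mixed-layer temperatures so the bundle mean upper-30-m
  # temperature equals the regime target exactly; the upper-30-m mean is
  # the trapezoidal average of the 1-m profile, matching prep_temperature(),
  # and is linear in t_mix, so one shift suffices
  sbar30 <- trapz_mean(stats::plogis((0:30 - zc) / zw))
  upper30_coef <- ifelse(stratified, 1 - sbar30, 1)
  upper30_now <- ifelse(stratified,
                        t_mix * (1 - sbar30) + t_bot * sbar30, t_mix)
  t_mix <- t_mix + (config$target_upper30 - mean(upper30_now)) /
    mean(upper30_coef)

  profs <- lapply(seq_len(n), function(i) {
    nb <- floor(stations$bottom_depth[i])
    z <- seq_len(nb) - 1
    s <- if (stratified[i]) stats::plogis((z - zc) / zw) else 0
    data.frame(station_id = stations$station_id[i],
               depth_m = seq_len(nb) - 1L,
               temp_c = t_mix[i] * (1 - s) + t_bot[i] * s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, profs)
  rownames(out) <- NULL
  out
}

.gs_make_prey_field <- function(config, stations, traits) {
  n <- nrow(stations)
  u <- 1 - pmin(stations$bottom_depth / 200, 1)   # 1 = inshore
  # total biomass highest inshore, log-normal station noise
  total <- config$total_biomass * exp(0.9 * (u - mean(u))) *
    stats::rlnorm(n, 0, 0.4)
  w <- config$composition
  rows <- lapply(seq_len(n), function(i) {
    mult <- stats::rlnorm(length(w), 0, 0.5)
    biom <- total[i] * w * mult
    biom <- biom / sum(biom) * total[i]
    abund <- biom / traits$ind_biomass_g[match(names(w), traits$taxon)]
    data.frame(station_id = stations$station_id[i],
               taxon = names(w),
               abundance_n_per_m3 = abund,
               biomass_g_per_m3 = biom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.gs_make_fish_obs <- function(config, stations) {
  n <- nrow(stations)
  d2 <- (stations$lon - config$cpue_center[1])^2 +
    (stations$lat - config$cpue_center[2])^2
  mu <- config$cpue_scale * exp(-d2 / (2 * config$cpue_width^2)) *
    stats::rlnorm(n, 0, 0.7)
  p_catch <- 1 - exp(-mu / (0.1 * config$cpue_scale))
  caught <- stats::runif(n) < p_catch
  dist <- stats::runif(n, 1200, 2400)
  n_caught <- ifelse(caught, stats::rpois(n, mu * dist * config$trawl_spread),
                     0L)
  w_mean <- if (config$regime == "warm") 1.97 else 2.39
  mean_w <- pmax(stats::rnorm(n, w_mean, 0.3), 0.5)
  ed_mean <- if (config$regime == "warm") 3.92 else 5.29
  mean_ed <- pmax(stats::rnorm(n, ed_mean, 0.396), 1)
  n_proc <- ifelse(n_caught > 0, pmin(n_caught, sample(2:8, n, TRUE)), 0L)
  data.frame(
    station_id = stations$station_id,
    tow_type = "surface",
    n_caught = as.integer(n_caught),
    trawl_distance_m = dist,
    trawl_spread_m = config$trawl_spread,
    n_processed = as.integer(n_proc),
    mean_weight_g = mean_w,
    mean_length_mm = weight_to_length(mean_w),
    mean_fish_ed_kj_g = mean_ed,
    stringsAsFactors = FALSE
  )
}

.gs_make_diet <- function(config, stations, prey_field, fish_obs) {
  with_diet <- fish_obs$station_id[fish_obs$n_caught > 0 &
                                     fish_obs$n_processed > 0]
  if (length(with_diet) == 0) {
    return(data.frame(station_id = character(), taxon = character(),
                      percent_volume = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(with_diet, function(sid) {
    pf <- prey_field[prey_field$station_id == sid, ]
    share <- pf$biomass_g_per_m3 * exp(stats::rnorm(nrow(pf), 0, 0.5))
    share <- share / sum(share)
    total <- stats::runif(1, 90, 100)
    keep <- share > 0.001
    data.frame(station_id = sid, taxon = pf$taxon[keep],
               percent_volume = share[keep] / sum(share[keep]) * total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard length from wet weight (and back)
#'
#' Cubic length-weight relation calibrated so a 2.5 g juvenile pollock is
#' 65 mm standard length: `W = c * SL^3` with `c = 2.5 / 65^3`.
#'
#' @param w Wet weight, g.
#' @return Standard length, mm.
#' @export
weight_to_length <- function(w) {
  (w / (2.5 / 65^3))^(1 / 3)
}

#' @rdname weight_to_length
#' @param sl Standard length, mm.
#' @export
length_to_weight <- function(sl) {
  (2.5 / 65^3) * sl^3
}
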