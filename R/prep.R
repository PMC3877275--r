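# Survey preparation: every computation between raw survey tables and
# model-ready inputs.

#' Catch per unit effort from trawl observations
#'
#' CPUE (fish m^-2) for each surface tow: `n / (d * h)` where `n` is the
#' number of fish caught, `d` the trawl distance (m) and `h` the horizontal
#' trawl spread (m). Midwater tows target acoustic sign and are excluded with
#' a warning; nonpositive trawl geometry is rejected.
#'
#' @param fish_obs Data frame with columns `station_id`, `tow_type`,
#'   `n_caught`, `trawl_distance_m`, `trawl_spread_m`.
#' @return Data frame with columns `station_id`, `cpue` (fish m^-2), one row
#'   per retained surface tow.
#' @examples
#' compute_cpue(data.frame(station_id = "a", tow_type = "surface",
#'                         n_caught = 50, trawl_distance_m = 1000,
#'                         trawl_spread_m = 50))
#' @export
compute_cpue <- function(fish_obs) {
  required <- c("station_id", "tow_type", "n_caught", "trawl_distance_m",
                "trawl_spread_m")
  missing <- setdiff(required, names(fish_obs))
  if (length(missing) > 0) {
    stop("fish_obs is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mid <- fish_obs$tow_type != "surface"
  if (any(mid)) {
    warning(sprintf("excluding %d non-surface tow(s) from CPUE", sum(mid)),
            call. = FALSE)
    fish_obs <- fish_obs[!mid, , drop = FALSE]
  }
  if (any(fish_obs$trawl_distance_m <= 0) ||
      any(fish_obs$trawl_spread_m <= 0)) {
    stop("trawl distance and spread must be positive", call. = FALSE)
  }
  if (any(fish_obs$n_caught < 0)) {
    stop("n_caught must be nonnegative", call. = FALSE)
  }
  data.frame(
    station_id = fish_obs$station_id,
    cpue = fish_obs$n_caught /
      (fish_obs$trawl_distance_m * fish_obs$trawl_spread_m),
    stringsAsFactors = FALSE
  )
}

#' CPUE-weighted mean diet composition
#'
#' Averages station diet compositions (per cent volume by taxon) across
#' stations, weighting each station by its juvenile pollock CPUE. If every
#' station has zero CPUE the unweighted mean is returned with a warning.
#'
#' @param diet Data frame with columns `station_id`, `taxon`,
#'   `percent_volume`.
#' @param cpue Data frame with columns `station_id`, `cpue` covering every
#'   station present in `diet`.
#' @return Data frame with columns `taxon`, `percent_volume` (weighted mean),
#'   sorted by descending contribution.
#' @export
weighted_diet_composition <- function(diet, cpue) {
  if (!all(c("station_id", "taxon", "percent_volume") %in% names(diet))) {
    stop("diet must have station_id, taxon, percent_volume", call. = FALSE)
  }
  bad <- tapply(diet$percent_volume, diet$station_id, sum)
  if (any(diet$percent_volume < 0) || any(bad > 100 + 1e-6)) {
    stop("per-station percent volumes must be >= 0 and sum to <= 100",
         call. = FALSE)
  }
  stations <- unique(diet$station_id)
  if (!all(stations %in% cpue$station_id)) {
    stop("every diet station needs a CPUE value", call. = FALSE)
  }
  wts <- cpue$cpue[match(stations, cpue$station_id)]
  if (all(wts == 0)) {
    warning("all CPUE weights are zero; using unweighted mean",
            call. = FALSE)
    wts <- rep(1, length(stations))
  }
  taxa <- sort(unique(diet$taxon))
  # per-station composition matrix (absent taxon = 0% volume)
  comp <- matrix(0, length(stations), length(taxa),
                 dimnames = list(stations, taxa))
  comp[cbind(match(diet$station_id, stations),
             match(diet$taxon, taxa))] <- diet$percent_volume
  mean_pct <- colSums(comp * wts) / sum(wts)
  out <- data.frame(taxon = taxa, percent_volume = unname(mean_pct),
                    stringsAsFactors = FALSE)
  out[order(-out$percent_volume, out$taxon), , drop = FALSE]
}

#' Select main prey taxa from a mean diet composition
#'
#' Orders taxa by descending individual per cent volume and includes a taxon
#' if the cumulative volume before it is still below 90% (so the taxon
#' crossing 90% is included) or if it individually accounts for at least 2%
#' of the diet; selection stops at the first taxon failing both conditions.
#' Ties in individual per cent volume break alphabetically. The cumulative
#' column is computed at full precision; `cumulative_display` rounds the
#' running sum to one decimal for tabulation.
#'
#' @param composition Either a named numeric vector (taxon -> mean per cent
#'   volume) or a data frame with columns `taxon`, `percent_volume`.
#' @param cumulative_threshold Cumulative per cent volume to reach
#'   (default 90).
#' @param individual_threshold Individual per cent volume retaining further
#'   taxa past the cumulative threshold (default 2).
#' @return Data frame of the selected taxa in order, with columns `taxon`,
#'   `percent_volume`, `cumulative`, `cumulative_display`.
#' @export
select_main_prey <- function(composition, cumulative_threshold = 90,
                             individual_threshold = 2) {
  if (is.data.frame(composition)) {
    pct <- stats::setNames(composition$percent_volume, composition$taxon)
  } else {
    pct <- composition
  }
  if (length(pct) == 0) {
    return(data.frame(taxon = character(), percent_volume = numeric(),
                      cumulative = numeric(), cumulative_display = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (any(pct < 0)) stop("composition must be nonnegative", call. = FALSE)
  ord <- order(-pct, names(pct))
  pct <- pct[ord]
  cum <- cumsum(pct)
  before <- c(0, cum[-length(cum)])
  keep_each <- before < cumulative_threshold | pct >= individual_threshold
  n_keep <- if (all(keep_each)) length(pct) else which(!keep_each)[1] - 1L
  idx <- seq_len(n_keep)
  data.frame(taxon = names(pct)[idx],
             percent_volume = unname(pct[idx]),
             cumulative = unname(cum[idx]),
             cumulative_display = round(unname(cum[idx]), 1),
             stringsAsFactors = FALSE)
}

#' Union of main prey taxa across regimes
#'
#' Main prey from either regime are modelled in both, so the modelling set is
#' the union of the two selections; taxa named in `exclude` are dropped
#' (e.g., a taxon absent from the quantitative large-zooplankton gear in the
#' cold year).
#'
#' @param ... Selections from [select_main_prey()] (data frames with a
#'   `taxon` column) or character vectors of taxa.
#' @param exclude Taxa to drop from the union.
#' @return Character vector of taxa.
#' @export
main_prey_union <- function(..., exclude = character()) {
  sets <- lapply(list(...), function(x) {
    if (is.data.frame(x)) x$taxon else as.character(x)
  })
  setdiff(sort(unique(unlist(sets))), exclude)
}

#' Energy density vs per cent lipid regression
#'
#' Ordinary least squares of wet-weight energy density (kJ g^-1) on lipid
#' composition (%): `ED = alpha + beta * L`. Used to predict energy density
#' for copepod taxa or climate states lacking direct calorimetry.
#'
#' @param lipid_pct Per cent lipid of each sample.
#' @param ed Energy density of each sample, kJ g^-1 wet.
#' @return An object of class `ed_regression`: list with `alpha`, `beta`,
#'   `r_squared`, `sigma` (residual SD) and the underlying `lm` fit.
#' @export
fit_ed_lipid_regression <- function(lipid_pct, ed) {
  if (length(lipid_pct) != length(ed)) {
    stop("lipid_pct and ed must have equal length", call. = FALSE)
  }
  if (length(ed) < 3) {
    stop("at least 3 samples are required", call. = FALSE)
  }
  if (stats::var(lipid_pct) == 0) {
    stop("lipid values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(ed ~ lipid_pct)
  s <- summary(fit)
  out <- list(alpha = unname(stats::coef(fit)[1]),
              beta = unname(stats::coef(fit)[2]),
              r_squared = s$r.squared,
              sigma = s$sigma,
              fit = fit)
  class(out) <- "ed_regression"
  out
}

#' @export
print.ed_regression <- function(x, ...) {
  cat(sprintf("ED = %.3f + %.3f * lipid%%  (R^2 = %.3f, sigma = %.3f)\n",
              x$alpha, x$beta, x$r_squared, x$sigma))
  invisible(x)
}

#' Predict energy density from per cent lipid
#'
#' @param lipid_pct Per cent lipid (>= 0).
#' @param reg An `ed_regression` from [fit_ed_lipid_regression()], or a list
#'   with elements `alpha` and `beta`.
#' @return Predicted energy density, kJ g^-1 wet.
#' @examples
#' predict_ed_from_lipid(10, list(alpha = 19.3, beta = 0.41))
#' @export
predict_ed_from_lipid <- function(lipid_pct, reg) {
  if (any(lipid_pct < 0)) stop("lipid_pct must be >= 0", call. = FALSE)
  reg$alpha + reg$beta * lipid_pct
}

#' Biomass-weighted station prey energy density
#'
#' For each station, each taxon's biomass is divided by the total biomass of
#' main prey present, multiplied by its energy density and summed:
#' `prey_ed = sum_j (B_j / sum(B)) * ED_j`. Stations with zero total main-prey
#' biomass are flagged missing (`NA`) and should be excluded from growth
#' maps.
#'
#' @param prey_field Data frame with columns `station_id`, `taxon`,
#'   `biomass_g_per_m3`.
#' @param traits Trait table with columns `taxon`, `ed_kj_g`.
#' @param main_prey Optional character vector restricting the computation to
#'   a modelling set of taxa; default uses every taxon in the trait table.
#' @return Data frame with columns `station_id`, `prey_ed` (kJ g^-1, `NA`
#'   where flagged) and `total_biomass` (g m^-3).
#' @export
station_prey_energy <- function(prey_field, traits, main_prey = NULL) {
  main_prey <- main_prey %||% traits$taxon
  pf <- prey_field[prey_field$taxon %in% main_prey, , drop = FALSE]
  if (any(pf$biomass_g_per_m3 < 0)) {
    stop("biomass must be nonnegative", call. = FALSE)
  }
  ed <- traits$ed_kj_g[match(pf$taxon, traits$taxon)]
  if (any(is.na(ed))) {
    stop("trait table lacks ED for: ",
         paste(unique(pf$taxon[is.na(ed)]), collapse = ", "), call. = FALSE)
  }
  stations <- unique(prey_field$station_id)
  tot <- tapply(pf$biomass_g_per_m3, pf$station_id, sum)
  num <- tapply(pf$biomass_g_per_m3 * ed, pf$station_id, sum)
  prey_ed <- as.numeric(num[stations] / tot[stations])
  total <- as.numeric(tot[stations])
  total[is.na(total)] <- 0
  zero <- total <= 0
  if (any(zero)) {
    warning(sprintf("%d station(s) with zero main-prey biomass flagged NA",
                    sum(zero)), call. = FALSE)
    prey_ed[zero] <- NA_real_
  }
  data.frame(station_id = stations, prey_ed = prey_ed,
             total_biomass = total, stringsAsFactors = FALSE)
}

#' Mean individual biomass from a subsample
#'
#' Total subsample wet mass divided by the number of specimens subsampled.
#'
#' @param weights_g Wet weights of the specimens weighed, g (their sum is the
#'   subsample biomass).
#' @param count Total number of specimens subsampled.
#' @return Mean individual biomass, g.
#' @export
mean_individual_biomass <- function(weights_g, count) {
  stopifnot_scalar_number(count, "count")
  if (count <= 0) stop("count must be > 0", call. = FALSE)
  sum(weights_g) / count
}

#' Build day/night vertical profiles from depth-stratified samples
#'
#' Converts depth-stratified net samples into taxon x period vertical
#' distributions over 1-m bins: abundance within each sampled stratum is
#' spread uniformly into its 1-m bins, tows are averaged within a period, and
#' the result is normalized to fractions summing to 1. Fallback rules: a
#' taxon absent from one period's tows takes the profile named for it in
#' `fallbacks` (e.g., another period or taxon); a taxon listed in
#' `genus_average` takes the average profile of all taxa sharing its genus. A
#' taxon absent everywhere gets a uniform profile with a warning.
#'
#' @param samples Data frame with columns `tow_id`, `taxon`, `period`
#'   (`"day"`/`"night"`), `depth_top_m`, `depth_bottom_m`,
#'   `abundance_n_per_m3`.
#' @param column_depth Water-column depth for the profiles, m (bins run from
#'   0 to `column_depth - 1`).
#' @param taxa Taxa to produce profiles for; default all in `samples`.
#' @param fallbacks Named list: `fallbacks[[taxon]][[period]]` is a
#'   `list(taxon=, period=)` donor profile specification.
#' @param genus_average Character vector of taxa whose profiles are replaced
#'   by the mean profile of all congeners (first word of the taxon name).
#' @return Data frame with columns `taxon`, `period`, `depth_bin_top_m`,
#'   `fraction`.
#' @export
build_vertical_profiles <- function(samples, column_depth = 100,
                                    taxa = NULL, fallbacks = list(),
                                    genus_average = character()) {
  need <- c("tow_id", "taxon", "period", "depth_top_m", "depth_bottom_m",
            "abundance_n_per_m3")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0) {
    stop("samples missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  taxa <- taxa %||% sort(unique(samples$taxon))
  bins <- 0:(column_depth - 1)

  tow_profile <- function(sub) {
    # one tow: uniform-within-stratum redistribution into 1-m bins
    dens <- rep(0, length(bins))
    for (r in seq_len(nrow(sub))) {
      top <- sub$depth_top_m[r]; bot <- sub$depth_bottom_m[r]
      if (bot <= top) stop("stratum must have depth_bottom_m > depth_top_m",
                           call. = FALSE)
      in_bin <- bins >= top & bins < bot
      dens[in_bin] <- dens[in_bin] + sub$abundance_n_per_m3[r]
    }
    dens
  }

  raw_profile <- function(tx, period) {
    sub <- samples[samples$taxon == tx & samples$period == period, ,
                   drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    tows <- split(sub, sub$tow_id)
    dens <- Reduce(`+`, lapply(tows, tow_profile)) / length(tows)
    if (sum(dens) == 0) return(NULL)
    dens / sum(dens)
  }

  get_profile <- function(tx, period) {
    p <- raw_profile(tx, period)
    if (!is.null(p)) return(p)
    fb <- fallbacks[[tx]][[period]]
    if (!is.null(fb)) {
      p <- raw_profile(fb$taxon %||% tx, fb$period %||% period)
      if (!is.null(p)) return(p)
    }
    warning(sprintf("no samples for %s (%s); using uniform profile",
                    tx, period), call. = FALSE)
    rep(1 / length(bins), length(bins))
  }

  profs <- list()
  for (tx in taxa) {
    for (period in c("day", "night")) {
      profs[[paste(tx, period)]] <- get_profile(tx, period)
    }
  }
  # genus-average substitution for rarely caught taxa
  for (tx in intersect(genus_average, taxa)) {
    genus <- strsplit(tx, " ")[[1]][1]
    congeners <- setdiff(taxa[startsWith(taxa, genus)], tx)
    if (length(congeners) == 0) next
    for (period in c("day", "night")) {
      mat <- vapply(c(congeners, tx),
                    function(g) profs[[paste(g, period)]],
                    numeric(length(bins)))
      profs[[paste(tx, period)]] <- rowMeans(mat)
    }
  }
  out <- do.call(rbind, lapply(taxa, function(tx) {
    do.call(rbind, lapply(c("day", "night"), function(period) {
      data.frame(taxon = tx, period = period, depth_bin_top_m = bins,
                 fraction = profs[[paste(tx, period)]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Model-ready temperatures from station profiles
#'
#' Produces, per station: the mean temperature in the upper 30 m (input to
#' the bioenergetics model) and a 1-m binned temperature vector truncated at
#' `min(bottom depth, max_depth)` (input to the IBM). Gaps within a profile
#' are linearly interpolated; stations with no profile at all are filled from
#' the nearest station (great-circle distance) whose bottom depth differs by
#' at most `depth_tol` (a proportion); stations with no eligible donor are
#' excluded with a warning. The operation is idempotent: running it on its
#' own binned output returns the same values.
#'
#' @param temperature Data frame with columns `station_id`, `depth_m`
#'   (bin top, m), `temp_c`.
#' @param stations Data frame with columns `station_id`, `lon`, `lat`,
#'   `bottom_depth`.
#' @param max_depth Truncation depth for IBM bins, m (default 100).
#' @param depth_tol Relative bottom-depth tolerance for donor stations
#'   (default 0.25).
#' @return List with `upper30` (data frame `station_id`, `upper30_temp`) and
#'   `bins` (data frame `station_id`, `depth_m`, `temp_c`).
#' @export
prep_temperature <- function(temperature, stations, max_depth = 100,
                             depth_tol = 0.25) {
  have <- intersect(stations$station_id, unique(temperature$station_id))
  if (length(have) == 0) {
    stop("no temperature profiles in bundle", call. = FALSE)
  }
  fill_bins <- function(sid) {
    bd <- stations$bottom_depth[stations$station_id == sid]
    nb <- max(1L, floor(min(bd, max_depth)))
    z <- 0:(nb - 1)
    prof <- temperature[temperature$station_id == sid, , drop = FALSE]
    prof <- prof[!is.na(prof$temp_c), , drop = FALSE]
    if (nrow(prof) == 0) return(NULL)
    if (nrow(prof) == 1) {
      tc <- rep(prof$temp_c, length(z))
    } else {
      tc <- stats::approx(prof$depth_m, prof$temp_c, xout = z,
                          rule = 2)$y    # rule=2: extend ends flat
    }
    data.frame(station_id = sid, depth_m = z, temp_c = tc,
               stringsAsFactors = FALSE)
  }
  bins <- list()
  missing_ids <- character()
  for (sid in stations$station_id) {
    if (sid %in% have) {
      b <- fill_bins(sid)
      if (is.null(b)) missing_ids <- c(missing_ids, sid) else
        bins[[sid]] <- b
    } else {
      missing_ids <- c(missing_ids, sid)
    }
  }
  # donor fill: nearest station with similar bottom depth
  donors <- names(bins)
  excluded <- character()
  for (sid in missing_ids) {
    me <- stations[stations$station_id == sid, ]
    cand <- stations[stations$station_id %in% donors, ]
    ok <- abs(cand$bottom_depth - me$bottom_depth) <=
      depth_tol * me$bottom_depth
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) {
      excluded <- c(excluded, sid)
      next
    }
    dist <- geosphere::distHaversine(cbind(me$lon, me$lat),
                                     cbind(cand$lon, cand$lat))
    donor <- cand$station_id[which.min(dist)]
    b <- bins[[donor]]
    nb <- max(1L, floor(min(me$bottom_depth, max_depth)))
    b <- b[b$depth_m < nb, , drop = FALSE]
    if (max(b$depth_m) < nb - 1) {  # donor shallower: extend bottom value
      extra <- data.frame(station_id = donor,
                          depth_m = (max(b$depth_m) + 1):(nb - 1),
                          temp_c = b$temp_c[nrow(b)])
      b <- rbind(b, extra)
    }
    b$station_id <- sid
    bins[[sid]] <- b
  }
  if (length(excluded) > 0) {
    warning("no donor profile for station(s): ",
            paste(excluded, collapse = ", "), "; excluded", call. = FALSE)
  }
  bins <- do.call(rbind, bins[intersect(stations$station_id, names(bins))])
  rownames(bins) <- NULL
  # continuous (trapezoidal) average of the interpolated profile over the
  # upper 30 m (or the full column where shallower)
  up <- vapply(split(bins, bins$station_id), function(b) {
    trapz_mean(b$temp_c[b$depth_m <= 30])
  }, numeric(1))
  upper30 <- data.frame(station_id = names(up), upper30_temp = unname(up),
                        stringsAsFactors = FALSE)
  upper30 <- upper30[match(intersect(stations$station_id, upper30$station_id),
                           upper30$station_id), ]
  rownames(upper30) <- NULL
  list(upper30 = upper30, bins = bins)
}

#' Survey-wide mean fish energy density and weight
#'
#' The annual mean fish energy density is the station mean ED weighted by
#' `cpue * n_processed` (catch density times the number of fish processed);
#' mean weight is weighted the same way.
#'
#' @param fish_obs Fish observation table (see [compute_cpue()]) with
#'   additional columns `n_processed`, `mean_fish_ed_kj_g`, `mean_weight_g`.
#' @param cpue Data frame `station_id`, `cpue`; computed from `fish_obs` if
#'   omitted.
#' @return List with `mean_fish_ed` (kJ g^-1), `mean_weight` (g) and
#'   `n_stations` used.
#' @export
fish_energy_summary <- function(fish_obs, cpue = NULL) {
  cpue <- cpue %||% suppressWarnings(compute_cpue(fish_obs))
  obs <- merge(fish_obs, cpue, by = "station_id")
  obs <- obs[obs$n_processed > 0 & obs$cpue > 0, , drop = FALSE]
  if (nrow(obs) == 0) {
    stop("no stations with processed fish and positive CPUE", call. = FALSE)
  }
  w <- obs$cpue * obs$n_processed
  list(mean_fish_ed = sum(w * obs$mean_fish_ed_kj_g) / sum(w),
       mean_weight = sum(w * obs$mean_weight_g) / sum(w),
       n_stations = nrow(obs))
}

#' Prepare a survey bundle for the growth models
#'
#' Runs the full preparation chain on a [make_scenario()] bundle: CPUE,
#' CPUE-weighted diet composition and main-prey selection, the modelling
#' taxa set, biomass-weighted station prey energy density over that set,
#' upper-30-m and 1-m binned temperatures, and the survey mean fish energy
#' density.
#'
#' @param bundle A `survey_bundle`.
#' @param main_prey Optional modelling taxa set; defaults to the bundle's
#'   diet-based selection.
#' @return An object of class `survey_prep`: list with `stations`, `cpue`,
#'   `diet_composition`, `main_prey`, `station_prey_ed`, `upper30`,
#'   `temp_bins`, `fish_energy`, `vertical_profiles`, `prey_traits`,
#'   `prey_field`, `regime`.
#' @export
prep_survey <- function(bundle, main_prey = NULL) {
  stopifnot(inherits(bundle, "survey_bundle"))
  cpue <- compute_cpue(bundle$fish_obs)
  if (is.null(main_prey)) {
    if (nrow(bundle$diet) > 0) {
      comp <- weighted_diet_composition(bundle$diet, cpue)
      main_prey <- select_main_prey(comp)$taxon
    } else {
      main_prey <- bundle$prey_traits$taxon
    }
  }
  sped <- suppressWarnings(
    station_prey_energy(bundle$prey_field, bundle$prey_traits, main_prey)
  )
  temps <- prep_temperature(bundle$temperature, bundle$stations)
  fe <- fish_energy_summary(bundle$fish_obs, cpue)
  out <- list(stations = bundle$stations, cpue = cpue,
              diet_composition = if (nrow(bundle$diet) > 0)
                weighted_diet_composition(bundle$diet, cpue) else NULL,
              main_prey = main_prey,
              station_prey_ed = sped,
              upper30 = temps$upper30,
              temp_bins = temps$bins,
              fish_energy = fe,
              vertical_profiles = bundle$vertical_profiles,
              prey_traits = bundle$prey_traits,
              prey_field = bundle$prey_field,
              regime = bundle$config$regime)
  class(out) <- "survey_prep"
  out
}

#' @export
print.survey_prep <- function(x, ...) {
  cat(sprintf("Prepared survey (%s regime): %d stations\n", x$regime,
              nrow(x$stations)))
  cat(sprintf("  mean upper-30-m temperature: %.2f degC\n",
              mean(x$upper30$upper30_temp)))
  cat(sprintf("  mean station prey ED: %.2f kJ/g; mean fish ED: %.2f kJ/g\n",
              mean(x$station_prey_ed$prey_ed, na.rm = TRUE),
              x$fish_energy$mean_fish_ed))
  cat(sprintf("  main prey taxa (%d): %s\n", length(x$main_prey),
              paste(x$main_prey, collapse = ", ")))
  invisible(x)
}
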