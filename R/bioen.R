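#' Dome-shaped temperature scaling function
#'
#' The classic Wisconsin-model thermal dome used for both consumption and
#' respiration. With `V = (t_max - T) / (t_max - t_opt)` the factor is
#' `V^X * exp(X * (1 - V))` where
#' `X = (Z^2 / 400) * (1 + sqrt(1 + 40 / Y))^2`,
#' `Z = log(Q) * (t_max - t_opt)` and `Y = log(Q) * (t_max - t_opt + 2)`.
#' The factor equals 1 at `t_opt`, falls to 0 at `t_max`, and is clamped at 0
#' for all temperatures at or above `t_max`.
#'
#' @param temp Water temperature, deg C (vectorized).
#' @param q Temperature-dependence coefficient (Q).
#' @param t_opt Optimum temperature, deg C.
#' @param t_max Maximum temperature, deg C; the factor is 0 at and above it.
#' @return Dimensionless scaling factor in `[0, 1]`.
#' @examples
#' temp_scaling(10, 2.6, 10, 15)  # 1 at the optimum
#' temp_scaling(15, 2.6, 10, 15)  # 0 at the maximum
#' @export
temp_scaling <- function(temp, q, t_opt, t_max) {
  if (t_opt >= t_max) stop("t_opt must be < t_max", call. = FALSE)
  stopifnot_scalar_number(q, "q", positive = TRUE)
  z <- log(q) * (t_max - t_opt)
  y <- log(q) * (t_max - t_opt + 2)
  x <- (z^2 / 400) * (1 + sqrt(1 + 40 / y))^2
  v <- (t_max - temp) / (t_max - t_opt)
  f <- ifelse(v > 0, v^x * exp(x * (1 - v)), 0)
  pmin(pmax(f, 0), 1)
}

#' Maximum daily consumption
#'
#' Temperature- and weight-specific maximum consumption
#' `Cmax = alpha_c * W^beta_c * f_C(T)` in g prey per g fish per day. Zero at
#' and above the maximum temperature for consumption.
#'
#' @param w Fish wet weight, g (vectorized).
#' @param temp Water temperature, deg C (vectorized).
#' @param params A [bioen_params()] object.
#' @return Maximum consumption, g g^-1 d^-1.
#' @examples
#' cmax(1, 10)      # alpha_c at 1 g and the optimum: 0.119
#' cmax(2.5, 8.8)
#' @export
cmax <- function(w, temp, params = bioen_params()) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("fish weight must be positive and finite", call. = FALSE)
  }
  params$alpha_c * w^params$beta_c *
    temp_scaling(temp, params$q_c, params$t_co, params$t_cm)
}

#' Respiration rate
#'
#' Weight- and temperature-specific respiration
#' `R = a_m * a_r * W^b_r * f_R(T)` in g O2 per g fish per day. Set
#' `active = FALSE` for standard metabolic rate (no activity multiplier), as
#' used for the vertical-migration surcharge in the individual-based model.
#'
#' @inheritParams cmax
#' @param active Apply the active-metabolism multiplier `a_m`? Default TRUE.
#' @return Respiration, g O2 g^-1 d^-1.
#' @export
respiration <- function(w, temp, params = bioen_params(), active = TRUE) {
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("fish weight must be positive and finite", call. = FALSE)
  }
  mult <- if (active) params$a_m else 1
  mult * params$a_r * w^params$b_r *
    temp_scaling(temp, params$q_r, params$t_ro, params$t_rm)
}

#' Mass-balance daily growth
#'
#' Wisconsin-type single-day energy budget. Realized consumption is
#' `C = eta * Cmax`; egestion `F = f_a * C`; excretion `U = u_a * (C - F)`
#' and specific dynamic action `SDA = d_s * (C - F)` are proportions of
#' assimilated consumption. Specific growth (g g^-1 d^-1) is
#'
#' `G = (C - F - U - SDA) / rho - R * o2cal / (fish_ed * 1000)`
#'
#' where `rho = fish_ed / prey_ed` converts consumed prey mass into predator
#' mass and the respiration term converts g O2 to energy via the oxycalorific
#' coefficient. Growth may be negative (metabolic losses exceed intake).
#'
#' All of `w`, `temp`, `prey_ed`, `fish_ed` and `eta` are recycled to a
#' common length, so a vector of stations can be evaluated in one call.
#'
#' @inheritParams cmax
#' @param prey_ed Biomass-weighted mean prey energy density, kJ g^-1 wet.
#' @param fish_ed Fish energy density, kJ g^-1 wet.
#' @param eta Relative foraging rate in `[0, 1]` (realized / maximum
#'   consumption). `eta = 1` gives maximum growth potential.
#' @return A data frame of class `growth_result` with columns `w`, `temp`,
#'   `prey_ed`, `fish_ed`, `eta`, `growth` (g g^-1 d^-1) and the budget
#'   diagnostics `cmax`, `consumption`, `egestion`, `excretion`, `sda`
#'   (all g prey g^-1 d^-1), `respiration` (g O2 g^-1 d^-1) and
#'   `resp_energy` (kJ g^-1 d^-1).
#' @examples
#' growth(w = 2.5, temp = 8.8, prey_ed = 3.9, fish_ed = 3.92)
#' @export
growth <- function(w, temp, prey_ed, fish_ed, eta = 1,
                   params = bioen_params()) {
  n <- max(length(w), length(temp), length(prey_ed), length(fish_ed),
           length(eta))
  w <- rep_len(w, n); temp <- rep_len(temp, n)
  prey_ed <- rep_len(prey_ed, n); fish_ed <- rep_len(fish_ed, n)
  eta <- rep_len(eta, n)
  if (any(!is.finite(prey_ed)) || any(prey_ed <= 0)) {
    stop("prey energy density must be positive", call. = FALSE)
  }
  if (any(!is.finite(fish_ed)) || any(fish_ed <= 0)) {
    stop("fish energy density must be positive", call. = FALSE)
  }
  if (any(eta < 0 | eta > 1)) {
    stop("eta must lie in [0, 1]", call. = FALSE)
  }
  cm <- cmax(w, temp, params)
  cons <- eta * cm
  eg <- params$f_a * cons
  assim <- cons - eg
  exc <- params$u_a * assim
  sda <- params$d_s * assim
  resp <- respiration(w, temp, params)
  resp_energy <- resp * params$o2cal / 1000          # kJ g^-1 d^-1
  rho <- fish_ed / prey_ed
  g <- (cons - eg - exc - sda) / rho - resp_energy / fish_ed
  out <- data.frame(w = w, temp = temp, prey_ed = prey_ed, fish_ed = fish_ed,
                    eta = eta, growth = g, cmax = cm, consumption = cons,
                    egestion = eg, excretion = exc, sda = sda,
                    respiration = resp, resp_energy = resp_energy)
  class(out) <- c("growth_result", "data.frame")
  out
}

#' Relative foraging rate for zero growth
#'
#' Solves for the relative foraging rate `eta*` at which daily growth is
#' zero (the maintenance ration as a fraction of maximum consumption).
#' Growth is monotone increasing in `eta`; the root is found with
#' [stats::uniroot()] on `[0, 1]`. Stations where even `eta = 1` cannot
#' sustain growth (or where growth is positive at `eta = 0`, impossible with
#' positive respiration) are flagged unattainable and returned as `NA`.
#'
#' @inheritParams growth
#' @param tol Absolute tolerance on growth at the root.
#' @return A data frame with columns `eta_star` (NA where unattainable) and
#'   `attainable`.
#' @seealso [eta_half_positive()] for the station-set criterion.
#' @export
solve_eta <- function(w, temp, prey_ed, fish_ed, params = bioen_params(),
                      tol = 1e-12) {
  n <- max(length(w), length(temp), length(prey_ed), length(fish_ed))
  w <- rep_len(w, n); temp <- rep_len(temp, n)
  prey_ed <- rep_len(prey_ed, n); fish_ed <- rep_len(fish_ed, n)
  eta_star <- rep(NA_real_, n)
  attainable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g0 <- growth(w[i], temp[i], prey_ed[i], fish_ed[i], 0, params)$growth
    g1 <- growth(w[i], temp[i], prey_ed[i], fish_ed[i], 1, params)$growth
    if (g0 > 0 || g1 < 0) next
    if (g1 == 0) {
      eta_star[i] <- 1; attainable[i] <- TRUE; next
    }
    root <- stats::uniroot(
      function(e) growth(w[i], temp[i], prey_ed[i], fish_ed[i], e,
                         params)$growth,
      interval = c(0, 1), tol = tol
    )
    eta_star[i] <- root$root
    attainable[i] <- TRUE
  }
  data.frame(eta_star = eta_star, attainable = attainable)
}

#' Foraging rate needed for positive growth at half of all stations
#'
#' For a set of stations, the relative foraging rate at which exactly half
#' the stations have positive growth: the median of the per-station
#' zero-growth rates `eta*`, with unattainable stations (negative growth even
#' at `eta = 1`) entering the median as `+Inf`.
#'
#' @inheritParams solve_eta
#' @return A single `eta` value (may be `Inf` if more than half the stations
#'   cannot grow at any foraging rate).
#' @export
eta_half_positive <- function(w, temp, prey_ed, fish_ed,
                              params = bioen_params()) {
  sol <- solve_eta(w, temp, prey_ed, fish_ed, params)
  eta <- ifelse(sol$attainable, sol$eta_star, Inf)
  stats::median(eta)
}

#' Growth surface over temperature and prey energy density
#'
#' Evaluates maximum growth potential on a temperature x prey-ED grid at
#' fixed fish weight and energy density. Cells at or above the maximum
#' temperature for consumption are `NA` (growth not estimable there).
#'
#' @param temp_grid Temperatures, deg C.
#' @param prey_ed_grid Prey energy densities, kJ g^-1.
#' @inheritParams growth
#' @return A matrix with `length(temp_grid)` rows and
#'   `length(prey_ed_grid)` columns; dimnames carry the grid values.
#' @export
growth_surface <- function(temp_grid, prey_ed_grid, w = 2.5, fish_ed = 5.29,
                           eta = 1, params = bioen_params()) {
  if (any(!is.finite(temp_grid)) || any(!is.finite(prey_ed_grid))) {
    stop("grids must be finite", call. = FALSE)
  }
  g <- outer(temp_grid, prey_ed_grid, function(tt, ee) {
    growth(w, tt, ee, fish_ed, eta, params)$growth
  })
  g[temp_grid >= params$t_cm, ] <- NA_real_
  dimnames(g) <- list(temp = format(temp_grid), prey_ed = format(prey_ed_grid))
  g
}

#' Station-level maximum growth potential
#'
#' Joins prepared survey inputs (upper-30-m temperature and biomass-weighted
#' prey energy density per station) and evaluates the bioenergetics budget at
#' each station.
#'
#' @param prep A `survey_prep` object from [prep_survey()].
#' @inheritParams growth
#' @param w Fish weight, g; constant across stations by design.
#' @param fish_ed Fish energy density, kJ g^-1; if `NULL`, the
#'   CPUE-and-sample-size-weighted survey mean from the prepared bundle.
#' @return A `growth_result` data frame with a `station_id` column.
#' @export
station_growth <- function(prep, w = 2.5, eta = 1, fish_ed = NULL,
                           params = bioen_params()) {
  stopifnot(inherits(prep, "survey_prep"))
  fish_ed <- fish_ed %||% prep$fish_energy$mean_fish_ed
  inputs <- merge(prep$upper30, prep$station_prey_ed, by = "station_id")
  inputs <- inputs[!is.na(inputs$prey_ed) & !is.na(inputs$upper30_temp), ]
  res <- growth(w = w, temp = inputs$upper30_temp, prey_ed = inputs$prey_ed,
                fish_ed = fish_ed, eta = eta, params = params)
  cbind(station_id = inputs$station_id, res)
}
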