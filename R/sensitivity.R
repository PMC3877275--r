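# Sensitivity analyses and bioenergetics-vs-IBM comparison.

#' Pooled standard deviation across stations, regimes removed
#'
#' Subtracts each regime's mean from its stations' values and takes the SD of
#' the pooled residuals with `n - (number of regimes)` degrees of freedom.
#'
#' @param values Station values.
#' @param groups Regime labels, one per value.
#' @return Pooled SD.
#' @examples
#' pooled_sd(c(0, 2, 10, 12), c("a", "a", "b", "b"))  # sqrt(4/2)
#' @export
pooled_sd <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  groups <- as.character(groups)
  g <- length(unique(groups))
  n <- length(values)
  if (n <= g) stop("need more values than groups", call. = FALSE)
  res <- values - stats::ave(values, groups)
  sqrt(sum(res^2) / (n - g))
}

#' Perturb one input by +/- 1 SD and summarize growth deltas
#'
#' Re-runs the bioenergetics model with one input (`W`, `T`, `preyED` or
#' `fishED`) shifted by `+sd` and `-sd` and records per-station changes in
#' growth relative to the base run (relative foraging rate held at 1).
#' Constant-across-station inputs (`W`, `fishED`) shift every station by the
#' same scalar; stations where a perturbed temperature reaches the maximum
#' temperature for consumption are flagged non-estimable (`NA` delta).
#'
#' @param inputs Data frame with columns `station_id`, `w`, `temp`,
#'   `prey_ed`, `fish_ed` (one row per station).
#' @param parameter One of `"W"`, `"T"`, `"preyED"`, `"fishED"`.
#' @param sd Perturbation size (same units as the input).
#' @param params A [bioen_params()].
#' @return An object of class `sensitivity_summary`: list with `parameter`,
#'   `sd`, `base` (per-station base growth), `deltas` (data frame
#'   `station_id`, `delta_plus`, `delta_minus`) and `summary` (rows base /
#'   +1 SD / -1 SD with min, mean, max; the base row holds absolute growth,
#'   perturbation rows hold deltas).
#' @export
perturb_and_summarize <- function(inputs, parameter = c("W", "T", "preyED",
                                                        "fishED"),
                                  sd, params = bioen_params()) {
  parameter <- match.arg(parameter)
  stopifnot_scalar_number(sd, "sd")
  need <- c("station_id", "w", "temp", "prey_ed", "fish_ed")
  if (!all(need %in% names(inputs))) {
    stop("inputs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  run <- function(shift) {
    x <- inputs
    col <- switch(parameter, W = "w", T = "temp", preyED = "prey_ed",
                  fishED = "fish_ed")
    x[[col]] <- x[[col]] + shift
    bad <- rep(FALSE, nrow(x))
    if (parameter == "T") bad <- x$temp >= params$t_cm
    if (parameter %in% c("W")) x$w <- pmax(x$w, 1e-6)
    if (parameter %in% c("preyED", "fishED")) {
      bad <- bad | x$prey_ed <= 0 | x$fish_ed <= 0
    }
    g <- rep(NA_real_, nrow(x))
    okr <- which(!bad)
    if (length(okr) > 0) {
      g[okr] <- growth(x$w[okr], x$temp[okr], x$prey_ed[okr],
                       x$fish_ed[okr], eta = 1, params = params)$growth
    }
    g
  }
  base <- run(0)
  plus <- run(sd) - base
  minus <- run(-sd) - base
  mmm <- function(v) c(min = min(v, na.rm = TRUE),
                       mean = mean(v, na.rm = TRUE),
                       max = max(v, na.rm = TRUE))
  summary <- rbind(base = mmm(base), `+1 SD` = mmm(plus),
                   `-1 SD` = mmm(minus))
  structure(list(parameter = parameter, sd = sd, base = base,
                 deltas = data.frame(station_id = inputs$station_id,
                                     delta_plus = plus, delta_minus = minus,
                                     stringsAsFactors = FALSE),
                 summary = as.data.frame(summary)),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("Sensitivity of growth to %s (+/- %g):\n", x$parameter, x$sd))
  print(round(x$summary, 4))
  invisible(x)
}

#' Build station inputs for the bioenergetics sensitivity runs
#'
#' @param prep A `survey_prep` object.
#' @param w Fish weight, g.
#' @param fish_ed Fish energy density, kJ g^-1 (default survey mean).
#' @return Data frame `station_id`, `w`, `temp`, `prey_ed`, `fish_ed` for
#'   stations with complete inputs.
#' @export
bioen_inputs <- function(prep, w = 2.5, fish_ed = NULL) {
  stopifnot(inherits(prep, "survey_prep"))
  fish_ed <- fish_ed %||% prep$fish_energy$mean_fish_ed
  x <- merge(prep$upper30, prep$station_prey_ed, by = "station_id")
  x <- x[!is.na(x$prey_ed), ]
  data.frame(station_id = x$station_id, w = w, temp = x$upper30_temp,
             prey_ed = x$prey_ed, fish_ed = fish_ed,
             stringsAsFactors = FALSE)
}

#' Monte Carlo sensitivity at a representative station
#'
#' Runs the bioenergetics model `n` times with one input (`W` or `fishED`)
#' drawn from a normal distribution with the observed mean and SD, truncated
#' below at 1% of the mean to avoid nonphysical values. Weight and fish
#' energy density do not vary across stations in the base model, so a single
#' representative station suffices: the draws shift all stations alike.
#'
#' @param temp,prey_ed Station temperature (deg C) and prey energy density
#'   (kJ g^-1).
#' @param vary `"W"` or `"fishED"`.
#' @param mean,sd Mean and SD of the varied input.
#' @param w,fish_ed Values of the non-varied inputs.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param params A [bioen_params()].
#' @return List with `draws`, `growth`, and `summary`
#'   (min, max, mean, sd of growth).
#' @export
monte_carlo_station <- function(temp, prey_ed, vary = c("W", "fishED"),
                                mean, sd, w = 2.5, fish_ed = 5.29,
                                n = 1000, seed = 1,
                                params = bioen_params()) {
  vary <- match.arg(vary)
  with_seed(seed, {
    draws <- pmax(stats::rnorm(n, mean, sd), 0.01 * mean)
    g <- if (vary == "W") {
      growth(draws, temp, prey_ed, fish_ed, 1, params)$growth
    } else {
      growth(w, temp, prey_ed, fish_ed = draws, eta = 1, params)$growth
    }
    list(draws = draws, growth = g,
         summary = c(min = min(g), max = max(g), mean = mean(g),
                     sd = stats::sd(g)))
  })
}

#' IBM sensitivity scenarios
#'
#' Re-runs the IBM under an alternate scenario — smaller starting weights
#' (2.0 g +/- 30%) or uniform vertical prey distributions — with the same
#' per-station seeds as the base run, and summarizes per-station growth and
#' depth deltas in the Table-4 shape (negative depth deltas = shallower).
#'
#' @param prep A `survey_prep` object.
#' @param scenario `"weight2"` (2.0 g starting weight) or `"uniform_prey"`.
#' @param base Optional base run from [ibm_by_station()] (same seed and
#'   sizes); recomputed if omitted.
#' @param ... Passed to [ibm_by_station()] (`n_fish`, `hours`, `seed`,
#'   `stations`, `config`, `params`...).
#' @return List with `base`, `scenario` (data frames), `deltas` and `summary`
#'   (min/mean/max rows for base growth, base depth, growth delta, depth
#'   delta).
#' @export
ibm_scenarios <- function(prep, scenario = c("weight2", "uniform_prey"),
                          base = NULL, ...) {
  scenario <- match.arg(scenario)
  base <- base %||% ibm_by_station(prep, ...)
  alt <- if (scenario == "weight2") {
    ibm_by_station(prep, w_mean = 2.0, ...)
  } else {
    ibm_by_station(prep, uniform_prey = TRUE, ...)
  }
  stopifnot(identical(base$station_id, alt$station_id))
  deltas <- data.frame(station_id = base$station_id,
                       growth_delta = alt$growth - base$growth,
                       depth_delta = alt$mean_depth - base$mean_depth,
                       stringsAsFactors = FALSE)
  mmm <- function(v) c(min = min(v), mean = mean(v), max = max(v))
  summary <- rbind(base_growth = mmm(base$growth),
                   base_depth = mmm(base$mean_depth),
                   growth_delta = mmm(deltas$growth_delta),
                   depth_delta = mmm(deltas$depth_delta))
  list(scenario = scenario, base = base, alt = alt, deltas = deltas,
       summary = as.data.frame(summary))
}

#' Compare bioenergetics and IBM growth fields
#'
#' Computes the per-station growth difference (bioenergetics minus IBM), the
#' regime mean per cent reduction `100 * (1 - mean_IBM / mean_bioen)`, the
#' relative foraging rate needed for positive growth at half the stations
#' (from the bioenergetics inputs) and the reduction implied by that rate,
#' `100 * (1 - eta)`.
#'
#' @param bioen Data frame with `station_id` and `growth` from
#'   [station_growth()].
#' @param ibm Data frame with `station_id` and `growth` from
#'   [ibm_by_station()].
#' @param inputs Optional [bioen_inputs()] data frame for the eta threshold;
#'   skipped if omitted.
#' @param params A [bioen_params()].
#' @return List of class `model_comparison`: `differences` (per-station),
#'   `mean_bioen`, `mean_ibm`, `percent_reduction`, `eta_half`,
#'   `implied_reduction`.
#' @examples
#' compare_models(data.frame(station_id = "a", growth = 0.0146),
#'                data.frame(station_id = "a", growth = 0.0102))
#' @export
compare_models <- function(bioen, ibm, inputs = NULL,
                           params = bioen_params()) {
  common <- intersect(bioen$station_id, ibm$station_id)
  if (length(common) == 0 ||
      length(common) < max(nrow(bioen), nrow(ibm)) * 0.5) {
    stop("bioenergetics and IBM results must cover matching stations",
         call. = FALSE)
  }
  b <- bioen$growth[match(common, bioen$station_id)]
  i <- ibm$growth[match(common, ibm$station_id)]
  differences <- data.frame(station_id = common, difference = b - i,
                            stringsAsFactors = FALSE)
  mb <- mean(b); mi <- mean(i)
  pr <- if (mb > 0) 100 * (1 - mi / mb) else NA_real_
  eta_half <- implied <- NA_real_
  if (!is.null(inputs)) {
    eta_half <- eta_half_positive(inputs$w, inputs$temp, inputs$prey_ed,
                                  inputs$fish_ed, params)
    implied <- 100 * (1 - eta_half)
  }
  structure(list(differences = differences, mean_bioen = mb, mean_ibm = mi,
                 percent_reduction = pr, eta_half = eta_half,
                 implied_reduction = implied),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Mean growth: bioenergetics %.4f vs IBM %.4f g/g/d\n",
              x$mean_bioen, x$mean_ibm))
  cat(sprintf("Per cent reduction: %.1f%% (%.0f%% to nearest per cent)\n",
              x$percent_reduction, round(x$percent_reduction)))
  if (!is.na(x$eta_half)) {
    cat(sprintf("eta for positive growth at half of stations: %.2f",
                x$eta_half))
    cat(sprintf(" (implied reduction %.0f%%)\n", round(x$implied_reduction)))
  }
  invisible(x)
}
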