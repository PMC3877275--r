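# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture_bundle <- function(regime, n = 12, seed = 42) {
  key <- paste("bundle", regime, n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- make_scenario(
      scenario_config(regime, n_stations = n, seed = seed)
    )
  }
  .fixtures[[key]]
}

fixture_prep <- function(regime, n = 12, seed = 42) {
  key <- paste("prep", regime, n, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- suppressWarnings(prep_survey(fixture_bundle(regime,
                                                                    n, seed)))
  }
  .fixtures[[key]]
}

# Published late-summer diet compositions (individual % volume) of juvenile
# pollock for the warm and cold survey years, in descending order, with a
# couple of minor taxa below the selection thresholds appended so the
# stopping rule is exercised.
diet_warm_year <- c("Limacina helicina" = 26.33, "Pseudocalanus sp." = 26.04,
               "Oikopleura sp." = 11.86, "Centropages abdominalis" = 8.98,
               "Thysanoessa raschii" = 8.48, "Thysanoessa sp." = 4.63,
               "Acartia clausi" = 3.40, "Calanus marshallae" = 1.71)
diet_cold_year <- c("Limacina helicina" = 35.45, "Thysanoessa inermis" = 27.08,
               "Calanus marshallae" = 13.87, "Neocalanus cristatus" = 4.84,
               "Thysanoessa inspinata" = 3.16, "Thysanoessa raschii" = 3.09,
               "Neocalanus plumchrus" = 2.98, "Eucalanus bungii" = 2.95)
minor_taxa <- c("Other copepod A" = 1.5, "Other copepod B" = 0.9)

# Independent evaluation of the thermal dome (written out from the closed
# form, not via the package function).
oracle_dome <- function(temp, q, t_opt, t_max) {
  z <- log(q) * (t_max - t_opt)
  y <- log(q) * (t_max - t_opt + 2)
  x <- (z^2 / 400) * (1 + sqrt(1 + 40 / y))^2
  v <- (t_max - temp) / (t_max - t_opt)
  ifelse(v > 0, v^x * exp(x * (1 - v)), 0)
}

# Spreadsheet-style independent evaluation of the daily energy budget.
oracle_growth <- function(w, temp, prey_ed, fish_ed, eta) {
  cm <- 0.119 * w^-0.46 * oracle_dome(temp, 2.6, 10, 15)
  consumed <- eta * cm
  egested <- 0.15 * consumed
  excreted <- 0.11 * (consumed - egested)
  sda <- 0.125 * (consumed - egested)
  resp <- 2 * 0.0075 * w^-0.251 * oracle_dome(temp, 2.6, 13, 18)
  (consumed - egested - excreted - sda) / (fish_ed / prey_ed) -
    resp * 13560 / (fish_ed * 1000)
}
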