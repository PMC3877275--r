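Package: growthscape
Title: Bioenergetics and Individual-Based Growth Models for Juvenile
    Walleye Pollock on the Eastern Bering Sea Shelf
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to map late-summer growth conditions ("growth hot spots")
    for juvenile walleye pollock across contrasting warm and cold shelf
    regimes. Implements a Wisconsin-type bioenergetics model (temperature-
    and weight-specific maximum consumption, respiration, egestion,
    excretion, specific dynamic action, and mass-balance growth), a
    depth-stratified mechanistic individual-based foraging model with
    light-dependent prey encounter, size-dependent capture success, diel
    vertical migration of zooplankton prey, and vertical behaviour with
    migration costs, plus the survey-preparation computations that feed both
    models (catch per unit effort, diet-based main-prey selection, an energy
    density versus per cent lipid regression, biomass-weighted station prey
    energy density, vertical-profile construction and temperature handling).
    Includes a seeded synthetic-scenario generator emulating warm-year and
    cold-year shelf survey grids, sensitivity analyses (plus/minus one pooled
    standard deviation perturbations and Monte Carlo), and a
    bioenergetics-versus-IBM model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
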