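# Table dialects, bundle readers/writers, and the pipeline driver.
#
# All tables are UTF-8 CSV with one header row and '.' decimal; numeric
# columns are written with 17 significant digits so write -> read round-trips
# are lossless; depths are positive downward in metres with half-open 1-m
# bins [top, top + 1).

#' Column schemas for every survey table
#'
#' @return A named list: for each table name, a named character vector of
#'   column types (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @export
survey_schemas <- function() {
  list(
    stations = c(station_id = "character", lon = "numeric", lat = "numeric",
                 bottom_depth = "numeric", domain = "character",
                 regime = "character"),
    temperature = c(station_id = "character", depth_m = "integer",
                    temp_c = "numeric"),
    prey_field = c(station_id = "character", taxon = "character",
                   abundance_n_per_m3 = "numeric",
                   biomass_g_per_m3 = "numeric"),
    prey_traits = c(taxon = "character", stage = "character",
                    length_mm = "numeric", width_mm = "numeric",
                    ind_biomass_g = "numeric", ed_kj_g = "numeric",
                    ed_single = "logical"),
    vertical_profiles = c(taxon = "character", period = "character",
                          depth_bin_top_m = "integer",
                          fraction = "numeric"),
    fish_obs = c(station_id = "character", tow_type = "character",
                 n_caught = "integer", trawl_distance_m = "numeric",
                 trawl_spread_m = "numeric", n_processed = "integer",
                 mean_weight_g = "numeric", mean_length_mm = "numeric",
                 mean_fish_ed_kj_g = "numeric"),
    diet = c(station_id = "character", taxon = "character",
             percent_volume = "numeric")
  )
}

#' Write a typed survey table
#'
#' CSV with one header row; numeric columns are formatted with 17 significant
#' digits so that reading the file back reproduces the doubles exactly.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param schema Named character vector of column types; columns in the
#'   schema must exist, extra columns are preserved.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(x, path, schema = NULL) {
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(x))
    if (length(missing) > 0) {
      stop("table is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out <- x
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a typed survey table
#'
#' Checks that every schema column is present (error names the missing
#' column), coerces column types, and rejects malformed numerics with the
#' offending row number. Unknown columns are preserved as read.
#'
#' @param path CSV path.
#' @param schema Named character vector of column types, e.g. an element of
#'   [survey_schemas()].
#' @return A data frame.
#' @export
read_survey_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(names(schema), names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    raw <- x[[col]]
    if (type %in% c("numeric", "integer")) {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw) & nzchar(raw) & raw != "NA")
      if (length(bad) > 0) {
        stop(sprintf("malformed numeric in column '%s' at row %d of %s",
                     col, bad[1], basename(path)), call. = FALSE)
      }
      x[[col]] <- if (type == "integer") as.integer(round(val)) else val
    } else if (type == "logical") {
      x[[col]] <- as.logical(raw)
    }
  }
  x
}

#' Write a survey bundle to a directory
#'
#' Emits one CSV per bundle table (`stations.csv`,
#' `temperature_profiles.csv`, `prey_field.csv`, `prey_traits.csv`,
#' `vertical_profiles.csv`, `fish_obs.csv`, `diet.csv`) plus a small
#' `config.json` recording the generating configuration. Deterministic: the
#' same bundle always produces byte-identical files.
#'
#' @param bundle A `survey_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "survey_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- survey_schemas()
  files <- c(stations = "stations.csv", temperature = "temperature_profiles.csv",
             prey_field = "prey_field.csv", prey_traits = "prey_traits.csv",
             vertical_profiles = "vertical_profiles.csv",
             fish_obs = "fish_obs.csv", diet = "diet.csv")
  for (nm in names(files)) {
    write_survey_table(bundle[[nm]], file.path(dir, files[[nm]]), s[[nm]])
  }
  cfg <- bundle$config
  cfg_plain <- lapply(unclass(cfg), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(cfg_plain, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a survey bundle from a directory
#'
#' Inverse of [write_bundle()]; the read bundle reproduces the written one
#' exactly (lossless numeric round-trip).
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `survey_bundle`.
#' @export
read_bundle <- function(dir) {
  s <- survey_schemas()
  files <- c(stations = "stations.csv", temperature = "temperature_profiles.csv",
             prey_field = "prey_field.csv", prey_traits = "prey_traits.csv",
             vertical_profiles = "vertical_profiles.csv",
             fish_obs = "fish_obs.csv", diet = "diet.csv")
  bundle <- lapply(names(files), function(nm) {
    read_survey_table(file.path(dir, files[[nm]]), s[[nm]])
  })
  names(bundle) <- names(files)
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$composition <- unlist(raw$composition)
    bundle$config <- structure(raw, class = "scenario_config")
  }
  class(bundle) <- "survey_bundle"
  bundle
}

#' Run the full analysis pipeline for one regime
#'
#' synth -> prep -> bioenergetics -> IBM -> sensitivity -> comparison, all
#' written as CSV under `out_dir` along with a `manifest.json` (package
#' version, seed, configuration hash). Two runs with equal manifests produce
#' byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param regime `"warm"` or `"cold"`.
#' @param n_stations Stations in the synthetic scenario.
#' @param seed Integer seed used for every stage.
#' @param n_fish,hours IBM problem size.
#' @param eta Relative foraging rate for the bioenergetics run.
#' @param run_ibm Include the IBM stages (the slow part)?
#' @param params A [bioen_params()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, regime = "warm", n_stations = 30,
                         seed = 1, n_fish = 100, hours = 72, eta = 1,
                         run_ibm = TRUE, params = bioen_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scenario_config(regime, n_stations = n_stations, seed = seed)
  bundle <- make_scenario(cfg)
  write_bundle(bundle, file.path(out_dir, "bundle"))
  prep <- prep_survey(bundle)

  write_survey_table(prep$cpue, file.path(out_dir, "cpue.csv"))
  write_survey_table(prep$station_prey_ed,
                     file.path(out_dir, "station_prey_ed.csv"))
  write_survey_table(prep$upper30, file.path(out_dir, "temps_model.csv"))
  if (!is.null(prep$diet_composition)) {
    mp <- select_main_prey(prep$diet_composition)
    write_survey_table(mp, file.path(out_dir, "main_prey.csv"))
  }

  bioen <- station_growth(prep, eta = eta, params = params)
  write_survey_table(bioen, file.path(out_dir, "growth_by_station.csv"))

  inputs <- bioen_inputs(prep)
  sens <- lapply(c(W = "W", T = "T", preyED = "preyED", fishED = "fishED"),
                 function(p) {
    sd <- switch(p,
                 W = 0.935,
                 T = pooled_sd(inputs$temp, rep(regime, nrow(inputs))),
                 preyED = pooled_sd(inputs$prey_ed,
                                    rep(regime, nrow(inputs))),
                 fishED = 0.39593)
    perturb_and_summarize(inputs, p, sd, params)
  })
  sens_tab <- do.call(rbind, lapply(names(sens), function(p) {
    s <- sens[[p]]$summary
    data.frame(parameter = p, row = rownames(s), s, row.names = NULL)
  }))
  write_survey_table(sens_tab, file.path(out_dir, "sensitivity_summary.csv"))

  ibm <- comparison <- NULL
  if (run_ibm) {
    ibm <- ibm_by_station(prep, n_fish = n_fish, hours = hours, seed = seed)
    write_survey_table(ibm, file.path(out_dir, "ibm_by_station.csv"))
    comparison <- compare_models(bioen, ibm, inputs, params)
    write_survey_table(comparison$differences,
                       file.path(out_dir, "comparison.csv"))
    jsonlite::write_json(
      list(mean_bioen = comparison$mean_bioen,
           mean_ibm = comparison$mean_ibm,
           percent_reduction = comparison$percent_reduction,
           eta_half = comparison$eta_half,
           implied_reduction = comparison$implied_reduction),
      file.path(out_dir, "comparison_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }

  cfg_file <- file.path(out_dir, "bundle", "config.json")
  manifest <- list(
    package = "growthscape",
    version = as.character(utils::packageVersion("growthscape")),
    seed = seed, regime = regime, n_stations = n_stations,
    n_fish = n_fish, hours = hours, eta = eta,
    config_hash = unname(tools::md5sum(cfg_file))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(bundle = bundle, prep = prep, bioen = bioen,
                 sensitivity = sens, ibm = ibm, comparison = comparison,
                 manifest = manifest))
}
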