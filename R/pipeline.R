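# Orchestration: a validated run configuration, the staged pipeline
# (simulate -> exposure -> trends -> hotspots -> severity) and a run
# manifest with input/output hashes for reproducibility checks.

config_schema <- function() {
  c("seed", "out_dir", "n_zones", "window", "survey_years", "period",
    "trend", "n_events", "hotspot", "severity", "scales", "placement",
    "tessellation", "crs", "simulate")
}

#' Validate a run configuration
#'
#' Fills defaults, rejects unknown keys, and requires a seed (every
#' stochastic stage draws from it).
#'
#' @param config named list (e.g. from `yaml::read_yaml`).
#' @return validated config list.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), config_schema())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  defaults <- list(
    n_zones = 100L, window = c(0, 0, 20000, 20000),
    survey_years = c(2005, 2011, 2014, 2015, 2017), period = 2011:2017,
    n_events = 9950, placement = "zone_vkmt", tessellation = "voronoi",
    out_dir = "results/run",
    hotspot = list(mass = 0.95, fraction = 0.05, n = 3, radius = 1200,
                   multiplier = 10),
    severity = list(balance = 0.30, stratify = "sex"),
    simulate = TRUE)
  for (nm in names(defaults))
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  config
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes simulate (synthetic city, surveys, collisions), exposure
#' (population and kilometers, interpolated over the period), trends
#' (standardized rates and standardized mortality ratios), hotspots
#' (fatal-event clustering and flagged areas) and severity (the
#' fatality-risk model), writing each stage's outputs under
#' `config$out_dir` and recording a manifest of hashes and timestamps.
#' A stage failure halts the run; the manifest then records the partial
#' completion.
#'
#' @param config validated config list ([validate_config()]).
#' @param resume reuse an existing manifest's outputs; refused when the
#'   config or input hashes no longer match.
#' @return the run manifest (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, resume = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_hash <- hash_object(config[setdiff(names(config), "out_dir")])
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (!identical(prev$config_hash, cfg_hash))
      stop("refusing to resume: config hash changed; run fresh")
    for (f in names(prev$file_hashes)) {
      fp <- file.path(out_dir, f)
      if (!file.exists(fp) ||
          !identical(unname(tools::md5sum(fp)), prev$file_hashes[[f]]))
        stop("refusing to resume: corrupted or missing output ", f,
             "; run fresh")
    }
  }
  manifest <- list(config_hash = cfg_hash, started = format(Sys.time()),
                   stages = list(), file_hashes = list())
  seed <- config$seed
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "completed",
                                      at = format(Sys.time()),
                                      outputs = files)
    for (f in files)
      manifest$file_hashes[[f]] <<- unname(tools::md5sum(file.path(out_dir, f)))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      at = format(Sys.time()),
                                      error = conditionMessage(e))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  env <- new.env()
  tryCatch({
    city <- generate_city(config$n_zones, as.numeric(config$window), seed,
                          tessellation = config$tessellation)
    truth <- make_ground_truth(city, survey_years = config$survey_years,
                               period = config$period,
                               trend = do.call(default_trend,
                                 config$trend %||% list()),
                               n_hotspots = config$hotspot$n,
                               hotspot_radius = config$hotspot$radius,
                               hotspot_multiplier = config$hotspot$multiplier,
                               seed = seed)
    surveys <- generate_surveys(city$zones, config$survey_years,
                                seed = seed, truth = truth)
    collisions <- generate_collisions(city$zones, city$network, truth,
                                      period = config$period, seed = seed,
                                      n_events = config$n_events,
                                      placement = config$placement)
    write_zones_geojson(city$zones, file.path(out_dir, "zones.geojson"))
    write_network_geojson(city$network, file.path(out_dir, "network.geojson"))
    write_surveys(surveys, file.path(out_dir, "surveys.csv"))
    write_collisions(collisions, file.path(out_dir, "collisions.csv"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
    env$city <- city; env$truth <- truth; env$surveys <- surveys
    env$collisions <- collisions
    record("simulate", c("zones.geojson", "network.geojson", "surveys.csv",
                         "collisions.csv", "ground_truth.json"))
  }, error = function(e) fail("simulate", e))

  tryCatch({
    pop <- estimate_population(env$surveys,
                               zone_ids = vapply(env$city$zones$zones, `[[`,
                                                 character(1), "zone_id"))
    pop_full <- interpolate_panel(pop, config$period)
    vk <- estimate_vkmt(env$surveys, env$city$zones, env$city$network)
    vk_full <- interpolate_panel(vk, config$period)
    write_exposure(pop_full, file.path(out_dir, "exposure_population.csv"))
    write_exposure(vk_full, file.path(out_dir, "exposure_vkmt.csv"))
    env$pop <- pop_full; env$vkmt <- vk_full
    record("exposure", c("exposure_population.csv", "exposure_vkmt.csv"))
  }, error = function(e) fail("exposure", e))

  tryCatch({
    rates_pop <- monthly_rates(env$collisions, env$pop, "population")
    rates_vk <- monthly_rates(env$collisions, env$vkmt, "vkmt")
    panel <- rbind(rates_pop, rates_vk)
    summ <- yearly_summary(panel)
    sm <- smr(env$collisions, env$pop)
    utils::write.csv(panel, file.path(out_dir, "rates_monthly.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "rates_yearly.csv"),
                     row.names = FALSE)
    utils::write.csv(sm$panel, file.path(out_dir, "smr_monthly.csv"),
                     row.names = FALSE)
    env$rates <- panel; env$smr <- sm
    record("trends", c("rates_monthly.csv", "rates_yearly.csv",
                       "smr_monthly.csv"))
  }, error = function(e) fail("trends", e))

  tryCatch({
    fatal <- env$collisions[env$collisions$fatal == 1, ]
    pat <- point_pattern(fatal$x, fatal$y, as.numeric(config$window))
    hs <- detect_hotspots(pat, mass = config$hotspot$mass,
                          fraction = config$hotspot$fraction)
    utils::write.csv(hs$flagged, file.path(out_dir, "hotspots_flagged.csv"),
                     row.names = FALSE)
    utils::write.csv(hs$grid$quadrats, file.path(out_dir, "quadrats.csv"),
                     row.names = FALSE)
    env$hotspots <- hs
    record("hotspots", c("hotspots_flagged.csv", "quadrats.csv"))
  }, error = function(e) fail("hotspots", e))

  tryCatch({
    spec <- severity_spec()
    scr <- screen_covariates(env$collisions,
                             c(spec$linear_terms, spec$smooth_terms))
    spec$linear_terms <- intersect(spec$linear_terms, scr$selected)
    spec$smooth_terms <- intersect(spec$smooth_terms, scr$selected)
    fit <- fit_gamm(env$collisions, spec)
    bal <- oversample(env$collisions, config$severity$balance, seed)
    fit_bal <- fit_gamm(bal, spec)
    utils::write.csv(fit$linear_coefficients,
                     file.path(out_dir, "severity_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(fit_bal$linear_coefficients,
                     file.path(out_dir, "severity_coefficients_balanced.csv"),
                     row.names = FALSE)
    env$severity <- fit
    record("severity", c("severity_coefficients.csv",
                         "severity_coefficients_balanced.csv"))
  }, error = function(e) fail("severity", e))

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  attr(manifest, "env") <- env
  invisible(manifest)
}
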