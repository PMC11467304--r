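#' Read a flat key-value run configuration
#'
#' YAML file of flat keys; see [runForecast()], [runUncsens()] and
#' [runSweep()] for the keys each command uses.
#'
#' @param path path to the YAML config file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), paste("missing config file:", path))
  yaml::read_yaml(path)
}

requirePath <- function(cfg, key) {
  p <- cfg[[key]]
  if (is.null(p)) stop("config key '", key, "' is required", call. = FALSE)
  missing <- p[!file.exists(p)]
  if (length(missing))
    stop("missing input (", key, "): ", missing[1L], call. = FALSE)
  p
}

paramsFromConfig <- function(cfg) {
  windModelParams(
    rho_air = cfg$rho_air %||% 1.15,
    cutoff_km = cfg$cutoff_km %||% 300,
    asym_on = cfg$asym_on %||% TRUE,
    wind_factor = cfg$wind_factor %||% 1.0)
}

# write a hazard field as CSV (lat, lon, wind_ms)
#' Write a hazard field as CSV
#'
#' Columns `lat`, `lon`, `wind_ms`, one row per cell.
#'
#' @param hazard a [HazardField-class].
#' @param path output path.
#' @return `path` invisibly.
#' @export
writeHazardCsv <- function(hazard, path) {
  ctr <- gridCentres(hazard)
  utils::write.csv(data.frame(lat = ctr[, 2L], lon = ctr[, 1L],
                              wind_ms = as.vector(hazard@values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run a single-forecast impact experiment
#'
#' Computes one wind field and impact per ensemble member with a fixed
#' impact function, and writes the member totals, the ensemble-mean impact
#' map and a summary. Config keys: `tracks` (track CSV), `exposure`
#' (population `.asc`), `impact_function` (JSON), `out_dir`; optional wind
#' model keys `rho_air`, `cutoff_km`, `asym_on`, `wind_factor`.
#'
#' @param cfg named list (or path to a YAML file) of config keys.
#' @return invisibly, a list with the `impactDistribution`, the summary row
#'   and the written paths (`member_totals.csv`, `mean_impact_map.asc`,
#'   `summary.json`).
#' @export
runForecast <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  ens <- readTracks(requirePath(cfg, "tracks"))
  exp <- readPopulation(requirePath(cfg, "exposure"))
  f <- readImpactFunctions(requirePath(cfg, "impact_function"))
  if (is(f, "FunctionBundle")) f <- bundleBest(f)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dist <- ensembleImpacts(ens, exp, f, paramsFromConfig(cfg))
  totals_path <- file.path(out_dir, "member_totals.csv")
  utils::write.csv(data.frame(member_id = dist$member_ids,
                              total = dist$totals),
                   totals_path, row.names = FALSE)
  map_path <- file.path(out_dir, "mean_impact_map.asc")
  writeGridAscii(dist$mean_map, map_path)
  summ <- summarizeImpacts(dist)
  summ_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(as.list(summ), summ_path, auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("forecast: %d members, mean %.0f displaced, %.0f%% zero-impact members",
                  length(dist$totals), dist$mean, 100 * dist$zero_fraction))
  invisible(list(distribution = dist, summary = summ,
                 paths = c(totals_path, map_path, summ_path)))
}

#' Run the global uncertainty and sensitivity experiment
#'
#' Saltelli design over (member, exposure scale, impact function), run
#' totals, first-order Sobol indices with bootstrap confidence intervals,
#' and optionally the per-cell dominant-input map. Config keys: `tracks`,
#' `exposure`, `bundle` (JSON bundle), `out_dir`; optional `base_n` (2048),
#' `seed` (42), `scale_lo`/`scale_hi` (0.8/1.2), `n_boot` (1000),
#' `dominant_map` (FALSE), plus the wind model keys of [runForecast()].
#'
#' @param cfg named list (or path to a YAML file) of config keys.
#' @return invisibly, the [uncertaintyAnalysis()] result plus written paths
#'   (`samples.csv`, `sensitivity.csv`, optionally `dominant_map.asc`).
#' @export
runUncsens <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  ens <- readTracks(requirePath(cfg, "tracks"))
  exp <- readPopulation(requirePath(cfg, "exposure"))
  bundle <- readImpactFunctions(requirePath(cfg, "bundle"))
  stopIfNot(is(bundle, "FunctionBundle"), "bundle file must hold a bundle")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- paramsFromConfig(cfg)
  base_n <- cfg$base_n %||% 2048
  seed <- cfg$seed %||% 42
  ua <- uncertaintyAnalysis(ens, exp, bundle, params,
                            scale_range = c(cfg$scale_lo %||% 0.8,
                                            cfg$scale_hi %||% 1.2),
                            base_n = base_n, seed = seed,
                            n_boot = cfg$n_boot %||% 1000)
  paths <- file.path(out_dir, c("samples.csv", "sensitivity.csv"))
  utils::write.csv(data.frame(run = seq_along(ua$totals),
                              total = ua$totals),
                   paths[1L], row.names = FALSE)
  utils::write.csv(ua$indices, paths[2L], row.names = FALSE)
  if (isTRUE(cfg$dominant_map)) {
    dom <- perCellDominant(ua$design, ens, exp, bundle, params,
                           hazards = ua$samples$hazards)
    dom_path <- file.path(out_dir, "dominant_map.asc")
    writeGridAscii(dom, dom_path)
    jsonlite::write_json(as.list(attr(dom, "legend")),
                         file.path(out_dir, "dominant_map_legend.json"),
                         auto_unbox = TRUE)
    paths <- c(paths, dom_path)
  }
  message(sprintf("uncsens: %d runs (base_n %d, seed %d), mean %.0f displaced",
                  length(ua$totals), base_n, seed, ua$mean))
  invisible(c(ua, list(paths = paths)))
}

#' Run the lead-time sweep experiment
#'
#' One uncertainty and sensitivity analysis per initialisation time, with
#' lead times measured to the parent track's landfall. Config keys:
#' `tracks` (vector of track CSVs, one per init time), `exposure`,
#' `bundle`, `land_mask` (`.asc`), `out_dir`; optional `base_n` (512),
#' `seed`, `n_boot` (200) and wind model keys.
#'
#' @param cfg named list (or path to a YAML file) of config keys.
#' @return invisibly, the [leadTimeSweep()] result plus the written path
#'   (`sweep_indices.csv`, rows indexed by lead time).
#' @export
runSweep <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  paths <- requirePath(cfg, "tracks")
  stopIfNot(length(paths) >= 1, "need at least one track file")
  ensembles <- lapply(paths, readTracks)
  it <- vapply(ensembles, function(e) as.numeric(initTime(e)), numeric(1))
  if (is.unsorted(it)) {
    warning("init times out of order; sorting")
    ensembles <- ensembles[order(it)]
  }
  exp <- readPopulation(requirePath(cfg, "exposure"))
  bundle <- readImpactFunctions(requirePath(cfg, "bundle"))
  mask <- readLandMask(requirePath(cfg, "land_mask"))
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sw <- leadTimeSweep(ensembles, exp, bundle, mask,
                      params = paramsFromConfig(cfg),
                      base_n = cfg$base_n %||% 512,
                      seed = cfg$seed %||% 42,
                      n_boot = cfg$n_boot %||% 200)
  out_path <- file.path(out_dir, "sweep_indices.csv")
  utils::write.csv(sw$table, out_path, row.names = FALSE)
  message(sprintf("sweep: %d init times, lead times %s days",
                  length(ensembles),
                  paste(sprintf("%.1f", sw$lead_time_days), collapse = ", ")))
  invisible(c(sw, list(paths = out_path)))
}
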