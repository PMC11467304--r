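#' Configuration of the synthetic study system
#'
#' The generators emulate the three external data sources of the forecasting
#' system: an ensemble of perturbed cyclone tracks, a clustered island
#' population grid, and a displacement event catalogue with known ground
#' truth. Defaults describe a Fiji-like setting: a compact island group near
#' 17.5 S / 178 E, a category-4-strength storm (peak pressure deficit
#' 60 hPa) approaching from the north-east at 5 m/s, a 51-member ensemble
#' with position spread growing as a random walk, and ~900,000 people in a
#' handful of coastal clusters.
#'
#' @param seed integer seed driving every random draw.
#' @param init_time forecast initialisation time (POSIXct UTC).
#' @param island_lat,island_lon island centre, degrees.
#' @param island_radius_km radius of the circular island, km.
#' @param approach_bearing_deg bearing from the island to the genesis point.
#' @param speed_ms translation speed of the parent storm, m/s.
#' @param dp0,dp_peak initial / peak pressure deficit, hPa.
#' @param horizon_h forecast horizon, hours.
#' @param step_h native track time step, hours.
#' @param landfall_frac fraction of the horizon at which the parent track
#'   reaches the island centre.
#' @param sigma_xy_km ensemble position random-walk standard deviation per
#'   step, km (along- and cross-track).
#' @param sigma_p_hpa ensemble central-pressure random-walk standard
#'   deviation per step, hPa.
#' @param pop_total total island population, persons.
#' @param n_clusters number of population clusters.
#' @param cluster_sigma_km Gaussian cluster width, km.
#' @param n_cells grid cells per side of the square domain.
#' @param res_arcsec grid resolution, arc seconds (150 on land).
#' @return list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1, init_time = as.POSIXct(
                              "2020-12-15 00:00:00", tz = "UTC"),
                            island_lat = -17.5, island_lon = 178,
                            island_radius_km = 80,
                            approach_bearing_deg = 20, speed_ms = 5,
                            dp0 = 10, dp_peak = 60, horizon_h = 120,
                            step_h = 6, landfall_frac = 0.5,
                            sigma_xy_km = 15, sigma_p_hpa = 2,
                            pop_total = 9e5, n_clusters = 5,
                            cluster_sigma_km = 15, n_cells = 200,
                            res_arcsec = 150) {
  structure(as.list(environment()), class = "syntheticConfig")
}

#' Synthetic parent (best-estimate) track
#'
#' Constant-heading, constant-speed great-circle motion reaching the island
#' centre at `landfall_frac` of the horizon, with the pressure deficit
#' ramping linearly from `dp0` to `dp_peak` at landfall and held constant
#' after. Environmental pressure is fixed at 1010 hPa. Deterministic: no
#' random draws.
#'
#' @param cfg a [syntheticConfig()].
#' @return A [TCTrack-class] with member id 0.
#' @export
makeParentTrack <- function(cfg) {
  times <- cfg$init_time + seq(0, cfg$horizon_h * 3600, by = cfg$step_h * 3600)
  n <- length(times)
  dist_to_island <- cfg$speed_ms * cfg$horizon_h * cfg$landfall_frac * 3600
  genesis <- geosphere::destPoint(c(cfg$island_lon, cfg$island_lat),
                                  cfg$approach_bearing_deg, dist_to_island,
                                  r = EARTH_RADIUS_M)
  heading <- bearingDeg(genesis, c(cfg$island_lon, cfg$island_lat))
  step_m <- cfg$speed_ms * cfg$step_h * 3600
  pos <- matrix(NA_real_, n, 2L)
  pos[1L, ] <- genesis
  if (n > 1L) for (k in 2:n)
    pos[k, ] <- geosphere::destPoint(pos[k - 1L, ], heading, step_m,
                                     r = EARTH_RADIUS_M)
  tland <- cfg$horizon_h * cfg$landfall_frac
  th <- seq(0, cfg$horizon_h, by = cfg$step_h)
  dp <- cfg$dp0 + (cfg$dp_peak - cfg$dp0) * pmin(th / max(tland, 1e-9), 1)
  tcTrack(times, pos[, 2L], pos[, 1L], p_cen = 1010 - dp, p_env = 1010,
          member_id = 0L, storm_id = "SYNTH")
}

# displace every fix of a track by along/cross-track offsets (km) and add
# a pressure perturbation (hPa)
perturbTrack <- function(parent, along_km, cross_km, dp_hpa, member_id) {
  p <- trackPoints(parent)
  n <- nrow(p)
  hd <- translationVelocity(parent)$bearing_deg
  pos <- cbind(normLon(p$lon), p$lat)
  out <- pos
  for (k in seq_len(n)) {
    q <- geosphere::destPoint(pos[k, ], hd[k], along_km[k] * 1000,
                              r = EARTH_RADIUS_M)
    out[k, ] <- geosphere::destPoint(q, hd[k] + 90, cross_km[k] * 1000,
                                     r = EARTH_RADIUS_M)
  }
  p_cen <- pmin(pmax(p$p_cen + dp_hpa, 870), p$p_env)
  tcTrack(p$time, out[, 2L], out[, 1L], p_cen, p$p_env, p$v_max, p$r_max,
          member_id = member_id, storm_id = stormId(parent))
}

#' Synthetic forecast ensemble
#'
#' Member 0 is the unperturbed parent; members `1..n-1` displace each fix by
#' cumulative along- and cross-track Gaussian random walks (standard
#' deviation `sigma_xy_km` per step, zero at the first fix) and perturb the
#' central pressure by a cumulative walk of `sigma_p_hpa` per step, so
#' ensemble spread grows with forecast step. With both sigmas 0 every member
#' equals the parent.
#'
#' @param parent a [TCTrack-class] from [makeParentTrack()].
#' @param cfg a [syntheticConfig()].
#' @param n ensemble size (default 51).
#' @param seed integer seed (default `cfg$seed`).
#' @return A [TCEnsemble-class].
#' @export
makeEnsemble <- function(parent, cfg, n = 51, seed = cfg$seed) {
  stopIfNot(n >= 1, "ensemble size must be >= 1")
  npts <- nrow(trackPoints(parent))
  withSeed(seed, {
    members <- vector("list", n)
    members[[1L]] <- parent
    if (n > 1L) for (m in 2:n) {
      walk <- function(sigma) c(0, cumsum(stats::rnorm(npts - 1L, 0, sigma)))
      members[[m]] <- perturbTrack(parent, walk(cfg$sigma_xy_km),
                                   walk(cfg$sigma_xy_km),
                                   walk(cfg$sigma_p_hpa),
                                   member_id = m - 1L)
    }
    tcEnsemble(members)
  })
}

#' Hit-or-miss steered ensemble
#'
#' Deterministically steers a configured fraction of members far enough
#' cross-track (island radius + wind cutoff + 250 km) that they cannot
#' produce any impact on the island, while the remaining members hug the
#' parent track with small distinct offsets. Used to study bimodal forecast
#' distributions.
#'
#' @param parent a [TCTrack-class].
#' @param n ensemble size.
#' @param miss_fraction fraction of members steered to miss; `n *
#'   miss_fraction` must be an integer.
#' @param cutoff_km wind cutoff of the hazard model, km.
#' @param island_radius_km island radius, km.
#' @return A [TCEnsemble-class] in which exactly `miss_fraction` of members
#'   stay farther than `cutoff_km` from every island cell.
#' @export
makeHitMissEnsemble <- function(parent, n = 50, miss_fraction = 0.4,
                                cutoff_km = 300, island_radius_km = 80) {
  n_miss <- round(n * miss_fraction)
  stopIfNot(abs(n_miss - n * miss_fraction) < 1e-9,
            "n * miss_fraction must be an integer")
  npts <- nrow(trackPoints(parent))
  big <- island_radius_km + cutoff_km + 250
  members <- lapply(seq_len(n), function(m) {
    cross <- if (m <= n_miss) big else (m - n_miss - 1L) * 2
    perturbTrack(parent, rep(0, npts), rep(cross, npts), rep(0, npts),
                 member_id = m - 1L)
  })
  tcEnsemble(members)
}

#' Synthetic island population grid and land mask
#'
#' A square grid centred on the island. Land is the circular disk of
#' `island_radius_km`; the population density is a sum of Gaussian clusters
#' whose centres are drawn (seeded) within 60% of the island radius, zeroed
#' over the ocean and rescaled so the grid total equals `pop_total` exactly.
#'
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `exposure` (an [ExposureGrid-class]) and `land_mask`
#'   (a [LandMask-class]).
#' @export
makePopulation <- function(cfg, seed = cfg$seed) {
  stopIfNot(cfg$island_radius_km > 0, "island radius must be positive")
  res <- cfg$res_arcsec / 3600
  half <- (cfg$n_cells - 1) / 2
  lon <- cfg$island_lon + (seq_len(cfg$n_cells) - 1 - half) * res
  lat <- cfg$island_lat + (seq_len(cfg$n_cells) - 1 - half) * res
  ctr <- cbind(lon = rep(lon, each = length(lat)),
               lat = rep(lat, times = length(lon)))
  d_centre <- haversineKm(c(cfg$island_lon, cfg$island_lat), ctr)
  land <- d_centre <= cfg$island_radius_km
  dens <- withSeed(seed, {
    k <- cfg$n_clusters
    ang <- stats::runif(k, 0, 360)
    rad <- stats::runif(k, 0, 0.6 * cfg$island_radius_km)
    dd <- numeric(nrow(ctr))
    for (i in seq_len(k)) {
      cc <- geosphere::destPoint(c(cfg$island_lon, cfg$island_lat), ang[i],
                                 rad[i] * 1000, r = EARTH_RADIUS_M)
      dk <- haversineKm(cc, ctr)
      dd <- dd + exp(-dk^2 / (2 * cfg$cluster_sigma_km^2))
    }
    dd
  })
  dens[!land] <- 0
  if (sum(dens) <= 0) dens[land] <- 1
  pop <- dens * (cfg$pop_total / sum(dens))
  nl <- length(lat)
  exposure <- geoGrid(lon, lat, matrix(pop, nl, length(lon)),
                      cfg$res_arcsec, class_ = "ExposureGrid")
  mask <- geoGrid(lon, lat, matrix(as.numeric(land), nl, length(lon)),
                  cfg$res_arcsec, class_ = "LandMask")
  list(exposure = exposure, land_mask = mask)
}

#' Synthetic displacement event catalogue
#'
#' Generates `n_events` historical storms crossing the island from random
#' directions with random peak intensity (pressure deficit uniform on
#' 30-80 hPa) and translation speed (3-7 m/s), computes each event's wind
#' footprint and its modeled displacement total under `true_function`, and
#' reports `round(modeled * exp(rnorm(0, sigma)))` — multiplicative
#' lognormal observation noise.
#'
#' @param n_events number of events.
#' @param true_function the ground-truth [ImpactFunction-class].
#' @param sigma lognormal noise standard deviation (log scale).
#' @param cfg a [syntheticConfig()].
#' @param seed integer seed.
#' @param exposure optional pre-built [ExposureGrid-class] (defaults to
#'   `makePopulation(cfg)$exposure`).
#' @param params a [WindModelParams-class].
#' @param region_id region label stored on the events.
#' @return list with `events` (list of `tcEvent`), `exposure`, `modeled`
#'   (noise-free totals) and `reported`.
#' @export
makeEventCatalog <- function(n_events, true_function, sigma = 0.2,
                             cfg = syntheticConfig(), seed = cfg$seed,
                             exposure = NULL,
                             params = windModelParams(),
                             region_id = "PACIFIC_ISLANDS") {
  stopIfNot(n_events >= 1, "need at least one event")
  if (is.null(exposure)) exposure <- makePopulation(cfg)$exposure
  withSeed(seed, {
    bearings <- stats::runif(n_events, 0, 360)
    dps <- stats::runif(n_events, 30, 80)
    speeds <- stats::runif(n_events, 3, 7)
    noise <- exp(stats::rnorm(n_events, 0, sigma))
    events <- vector("list", n_events)
    modeled <- numeric(n_events)
    for (i in seq_len(n_events)) {
      ecfg <- cfg
      ecfg$approach_bearing_deg <- bearings[i]
      ecfg$dp_peak <- dps[i]
      ecfg$speed_ms <- speeds[i]
      ecfg$horizon_h <- 48
      ecfg$landfall_frac <- 0.5
      track <- makeParentTrack(ecfg)
      hazard <- computeWindfield(track, exposure, params)
      modeled[i] <- computeImpact(hazard, exposure, true_function)$total
      events[[i]] <- eventRecord(sprintf("EV%03d", i), region_id,
                                 round(modeled[i] * noise[i]), hazard)
    }
    list(events = events, exposure = exposure, modeled = modeled,
         reported = vapply(events, function(e) e$reported, numeric(1)))
  })
}
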