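# shared synthetic fixtures, built once per test run; sizes kept small so
# the suite stays fast while the acceptance tests use the full study sizes

fixCfg <- function(...) {
  args <- list(seed = 7, n_cells = 60, horizon_h = 48, landfall_frac = 0.5)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(syntheticConfig, args)
}

# lazily-built shared island + parent + small ensemble
.fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fixCfg()
      pop <- makePopulation(cfg)
      parent <- makeParentTrack(cfg)
      cache <<- list(cfg = cfg, exposure = pop$exposure,
                     land_mask = pop$land_mask, parent = parent,
                     ensemble = makeEnsemble(parent, cfg, n = 11))
    }
    cache
  }
})

# single-cell land mask fixture: one land cell at (lat0, lon0), rest ocean
oneCellMask <- function(lat0, lon0, n = 21, res_arcsec = 1800) {
  res <- res_arcsec / 3600
  half <- (n - 1) / 2
  lon <- lon0 + (seq_len(n) - 1 - half) * res
  lat <- lat0 + (seq_len(n) - 1 - half) * res
  m <- matrix(0, n, n)
  m[half + 1, half + 1] <- 1
  geoGrid(lon, lat, m, res_arcsec, class_ = "LandMask")
}

# uniform square exposure grid centred at (lat0, lon0)
uniformExposure <- function(lat0 = -17.5, lon0 = 178, n = 10, value = 100,
                            res_arcsec = 1800) {
  res <- res_arcsec / 3600
  half <- (n - 1) / 2
  geoGrid(lon0 + (seq_len(n) - 1 - half) * res,
          lat0 + (seq_len(n) - 1 - half) * res,
          matrix(value, n, n), res_arcsec, class_ = "ExposureGrid")
}

# a simple 2-point 6-hourly track builder
simpleTrack <- function(lats, lons, p_cen = 980, p_env = 1010,
                        step_h = 6, member_id = 0L, ...) {
  n <- length(lats)
  times <- as.POSIXct("2020-12-15 00:00:00", tz = "UTC") +
    (seq_len(n) - 1) * step_h * 3600
  tcTrack(times, lats, lons, p_cen = rep_len(p_cen, n), p_env = p_env,
          member_id = member_id, ...)
}
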