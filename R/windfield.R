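#' Holland shape parameter for the surface pressure-wind relation
#'
#' Regression form of the surface Holland B parameter:
#' \deqn{b_s = -4.4\times10^{-5}\,\Delta p^2 + 0.01\,\Delta p +
#'   0.03\,\partial_t \Delta p - 0.014\,|\phi| + 0.15\,v_t^{x} + 1,}
#' with \eqn{x = 0.6(1 - \Delta p / 215)}, clamped to `[b_min, b_max]`.
#'
#' @param dp pressure deficit `p_env - p_cen`, hPa (non-negative).
#' @param dp_dt intensification rate of the deficit, hPa/h.
#' @param lat latitude, degrees.
#' @param v_t translation speed, m/s.
#' @param b_min,b_max clamp bounds.
#' @return numeric shape parameter, vectorised over inputs.
#' @export
hollandB <- function(dp, dp_dt = 0, lat = 0, v_t = 0,
                     b_min = 1.0, b_max = 2.5) {
  stopIfNot(all(dp >= 0), "pressure deficit must be non-negative")
  x <- 0.6 * (1 - dp / 215)
  vterm <- ifelse(v_t > 0, v_t^x, 0)
  b <- -4.4e-5 * dp^2 + 0.01 * dp + 0.03 * dp_dt - 0.014 * abs(lat) +
    0.15 * vterm + 1.0
  pmin(pmax(b, b_min), b_max)
}

#' Maximum wind from the pressure deficit
#'
#' \deqn{v_{max} = \sqrt{100\, b_s\, \Delta p / (\rho\, e)}} with the deficit
#' in hPa (the factor 100 converts to Pa) and `e` Euler's number.
#'
#' @param dp pressure deficit, hPa.
#' @param b_s Holland shape parameter.
#' @param rho_air surface air density, kg/m3.
#' @return numeric maximum 1-min sustained wind, m/s.
#' @export
vmaxFromPressure <- function(dp, b_s, rho_air = 1.15) {
  stopIfNot(all(dp >= 0), "pressure deficit must be non-negative")
  sqrt(100 * b_s * dp / (rho_air * exp(1)))
}

#' Pressure deficit from a reported maximum wind
#'
#' Inverse of [vmaxFromPressure()]; used when a fix reports wind but no
#' central pressure.
#'
#' @param v_max maximum wind, m/s.
#' @param b_s Holland shape parameter.
#' @param rho_air surface air density, kg/m3.
#' @return numeric pressure deficit, hPa.
#' @export
pressureDeficitFromVmax <- function(v_max, b_s, rho_air = 1.15) {
  stopIfNot(all(v_max >= 0), "wind must be non-negative")
  v_max^2 * rho_air * exp(1) / (100 * b_s)
}

#' Symmetric radial wind profile
#'
#' Outside the radius of maximum wind the revised Holland surface profile
#' \eqn{v(r) = v_{max} [(r_{max}/r)^{b_s} e^{1 - (r_{max}/r)^{b_s}}]^{0.5}};
#' inside, a linear ramp from 0 at the centre to `v_max` at `r_max`; exactly
#' zero beyond `cutoff_km`.
#'
#' @param r distance from the storm centre, km (vectorised).
#' @param r_max radius of maximum wind, km.
#' @param v_max maximum wind, m/s.
#' @param b_s Holland shape parameter.
#' @param cutoff_km wind cutoff distance, km.
#' @return numeric wind speed at `r`, m/s.
#' @export
windProfile <- function(r, r_max, v_max, b_s, cutoff_km = 300) {
  stopIfNot(all(r >= 0), "radius must be non-negative")
  stopIfNot(r_max > 0, "r_max must be positive")
  inner <- r < r_max
  q <- (r_max / pmax(r, r_max))^b_s
  v <- v_max * sqrt(q * exp(1 - q))
  v[inner] <- v_max * r[inner] / r_max
  v[r > cutoff_km] <- 0
  v
}

# pressure-tiered fallback for the radius of maximum wind (km)
tieredRmax <- function(dp, params) {
  if (!params@r_max_tiered) return(rep(params@r_max_default, length(dp)))
  ifelse(dp < 25, 50, ifelse(dp <= 50, 40, 30))
}

#' Compute the lifetime-maximum wind field of one track
#'
#' Evaluates the parametric wind model at every grid cell centre and every
#' (1-hourly interpolated) track fix, and keeps the per-cell maximum. When
#' `params@asym_on`, an attenuated translational component
#' \eqn{v_t\, r\, r_{max} / (r^2 + r_{max}^2) \cos(\theta - \theta_{track})}
#' is added to the symmetric profile, with the total capped at
#' \eqn{v_{max} + v_t}. Cells farther than `params@cutoff_km` from every fix
#' are exactly zero.
#'
#' @param track a [TCTrack-class]; interpolated to `step_h` internally if
#'   coarser.
#' @param grid a [GeoGrid-class] (typically an [ExposureGrid-class]) whose
#'   cell centres receive the hazard.
#' @param params a [WindModelParams-class].
#' @param step_h evaluation time step, hours.
#' @return A [HazardField-class] on the same grid.
#' @export
computeWindfield <- function(track, grid, params = windModelParams(),
                             step_h = 1) {
  stopIfNot(length(grid@values) > 0, "empty grid")
  tr <- if (is.na(track@time_step_h) || track@time_step_h > step_h)
    interpolateTrack(track, step_h) else track
  p <- trackPoints(tr)
  tv <- translationVelocity(tr)
  dp <- pmax(p$p_env - p$p_cen, 0)
  tt <- as.numeric(p$time) / 3600
  n <- nrow(p)
  i0 <- c(1L, seq_len(n - 2L), n - 1L)
  i1 <- c(2L, seq_len(n - 2L) + 2L, n)
  dp_dt <- (dp[i1] - dp[i0]) / (tt[i1] - tt[i0])
  b_s <- hollandB(dp, dp_dt, p$lat, tv$speed_ms, params@b_min, params@b_max)
  vmax <- ifelse(!is.na(p$v_max), p$v_max * params@wind_factor,
                 vmaxFromPressure(dp, b_s, params@rho_air))
  rmax <- ifelse(!is.na(p$r_max), p$r_max, tieredRmax(dp, params))

  ctr <- gridCentres(grid)
  cellLon <- ctr[, 1L]
  cellLat <- ctr[, 2L]
  wind <- numeric(nrow(ctr))
  dlat_max <- params@cutoff_km / 111.195
  for (k in seq_len(n)) {
    if (vmax[k] <= 0) next
    clat <- p$lat[k]; clon <- normLon(p$lon[k])
    dlon_max <- params@cutoff_km /
      (111.195 * max(cos(clat * pi / 180), 0.05))
    dlon <- abs(normLon(cellLon - clon))
    sel <- which(abs(cellLat - clat) <= dlat_max & dlon <= dlon_max)
    if (!length(sel)) next
    pts <- cbind(cellLon[sel], cellLat[sel])
    r <- haversineKm(c(clon, clat), pts)
    v <- windProfile(r, rmax[k], vmax[k], b_s[k], params@cutoff_km)
    if (params@asym_on && tv$speed_ms[k] > 0) {
      theta <- bearingDeg(c(clon, clat), pts)
      theta[!is.finite(theta)] <- 0  # cell exactly at the centre
      att <- r * rmax[k] / (r^2 + rmax[k]^2)
      v <- v + tv$speed_ms[k] * att *
        cos((theta - tv$bearing_deg[k]) * pi / 180)
      v <- pmin(pmax(v, 0), vmax[k] + tv$speed_ms[k])
      v[r > params@cutoff_km] <- 0
    }
    upd <- v > wind[sel]
    wind[sel[upd]] <- v[upd]
  }
  geoGrid(grid@lon, grid@lat,
          matrix(wind, length(grid@lat), length(grid@lon)),
          grid@res_arcsec, class_ = "HazardField",
          storm_id = stormId(tr), member_id = memberId(tr))
}
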