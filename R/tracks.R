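#' Convert wind speeds between knots and m/s
#'
#' One international knot is exactly 0.514444 m/s (1852 m per hour).
#'
#' @param v numeric wind speeds, knots (or m/s for `msToKnots`).
#' @return numeric converted speeds.
#' @examples
#' knotsToMs(146)  # 75.1 m/s
#' @export
knotsToMs <- function(v) {
  stopIfNot(all(v >= 0, na.rm = TRUE), "wind speed must be non-negative")
  v * 0.514444
}

#' @rdname knotsToMs
#' @export
msToKnots <- function(v) {
  stopIfNot(all(v >= 0, na.rm = TRUE), "wind speed must be non-negative")
  v / 0.514444
}

#' Read a forecast ensemble from a track CSV file
#'
#' One row per fix with columns `storm_id, member_id, iso_time, lat, lon,
#' p_cen_hpa, p_env_hpa, vmax_kt, rmax_km`; the last two may be blank.
#' Reported winds are converted from knots to m/s on read. Longitudes are
#' unwrapped per member so tracks crossing the antimeridian stay continuous.
#'
#' @param path path to the CSV file.
#' @return A [TCEnsemble-class] object.
#' @export
readTracks <- function(path) {
  stopIfNot(file.exists(path), paste("no such track file:", path))
  cols <- c("storm_id", "member_id", "iso_time", "lat", "lon",
            "p_cen_hpa", "p_env_hpa", "vmax_kt", "rmax_km")
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  stopIfNot(all(cols %in% names(raw)),
            paste("track CSV must have columns:", paste(cols, collapse = ", ")))
  asNum <- function(col, required = TRUE) {
    x <- raw[[col]]
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (required) bad <- union(bad, which(is.na(x)))
    if (length(bad))
      stop(sprintf("track CSV parse error in column '%s' at line %d",
                   col, bad[1L] + 1L), call. = FALSE)  # +1 for header
    out
  }
  tm <- as.POSIXct(raw$iso_time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(tm))
    stop(sprintf("track CSV parse error in column 'iso_time' at line %d",
                 which(is.na(tm))[1L] + 1L), call. = FALSE)
  dat <- data.frame(storm_id = raw$storm_id,
                    member_id = as.integer(asNum("member_id")),
                    time = tm, lat = asNum("lat"), lon = asNum("lon"),
                    p_cen = asNum("p_cen_hpa"), p_env = asNum("p_env_hpa"),
                    v_max = knotsToMs(asNum("vmax_kt", required = FALSE)),
                    r_max = asNum("rmax_km", required = FALSE))
  members <- lapply(split(dat, dat$member_id), function(d) {
    if (any(diff(as.numeric(d$time)) <= 0))
      stop("non-monotone fix times for member ", d$member_id[1L],
           call. = FALSE)
    tcTrack(d$time, d$lat, d$lon, d$p_cen, d$p_env, d$v_max, d$r_max,
            member_id = d$member_id[1L], storm_id = d$storm_id[1L])
  })
  members <- members[order(vapply(members, memberId, integer(1)))]
  names(members) <- NULL
  tcEnsemble(members)
}

#' Write a forecast ensemble to the track CSV dialect
#'
#' Longitudes are normalised back to `[-180, 180)` at the I/O boundary.
#'
#' @param ens a [TCEnsemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(ens, path) {
  rows <- do.call(rbind, lapply(ensembleMembers(ens), function(tr) {
    p <- trackPoints(tr)
    data.frame(storm_id = stormId(tr), member_id = memberId(tr),
               iso_time = format(p$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lat = p$lat, lon = normLon(p$lon),
               p_cen_hpa = p$p_cen, p_env_hpa = p$p_env,
               vmax_kt = ifelse(is.na(p$v_max), "", msToKnots(p$v_max)),
               rmax_km = ifelse(is.na(p$r_max), "", p$r_max))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a track to a finer time step
#'
#' Piecewise-linear interpolation of position (on unwrapped longitudes),
#' pressures and reported wind; the original fixes are preserved exactly.
#'
#' @param track a [TCTrack-class].
#' @param step_h target time step in hours (default 1); must divide the
#'   native step.
#' @return A [TCTrack-class] at the finer resolution.
#' @export
interpolateTrack <- function(track, step_h = 1) {
  stopIfNot(step_h > 0, "step_h must be positive")
  p <- trackPoints(track)
  t0 <- as.numeric(p$time)
  tout <- seq(t0[1L], t0[length(t0)], by = step_h * 3600)
  lin <- function(y) {
    if (all(is.na(y))) return(rep(NA_real_, length(tout)))
    stats::approx(t0, y, xout = tout)$y
  }
  tcTrack(as.POSIXct(tout, tz = "UTC", origin = "1970-01-01"),
          lin(p$lat), lin(p$lon), lin(p$p_cen), lin(p$p_env),
          lin(p$v_max), lin(p$r_max),
          member_id = memberId(track), storm_id = stormId(track))
}

#' Translation speed and bearing along a track
#'
#' Centred finite differences of great-circle position over time; one-sided
#' differences at the track ends.
#'
#' @param track a [TCTrack-class] (normally already interpolated).
#' @return data.frame with columns `speed_ms` and `bearing_deg` (degrees
#'   clockwise from north), one row per fix.
#' @export
translationVelocity <- function(track) {
  p <- trackPoints(track)
  n <- nrow(p)
  tt <- as.numeric(p$time)
  i0 <- c(1L, seq_len(n - 2L), n - 1L)     # segment start per point
  i1 <- c(2L, seq_len(n - 2L) + 2L, n)     # segment end per point
  pts <- cbind(normLon(p$lon), p$lat)
  d <- haversineKm(pts[i0, , drop = FALSE], pts[i1, , drop = FALSE]) * 1000
  dt <- tt[i1] - tt[i0]
  brg <- bearingDeg(pts[i0, , drop = FALSE], pts[i1, , drop = FALSE])
  brg[d < 1e-9] <- 0
  data.frame(speed_ms = d / dt, bearing_deg = brg)
}

#' Time of landfall of a track
#'
#' The first fix (of the 1-hourly interpolated track) whose position falls
#' inside a land cell of the mask.
#'
#' @param track a [TCTrack-class].
#' @param land_mask a [LandMask-class].
#' @param step_h interpolation step used for the scan, hours.
#' @return POSIXct time of the first land fix, or `NA` if the track never
#'   crosses land.
#' @export
timeOfLandfall <- function(track, land_mask, step_h = 1) {
  stopIfNot(is(land_mask, "LandMask") && length(land_mask@values) > 0,
            "land_mask must be a non-empty LandMask")
  tr <- interpolateTrack(track, step_h)
  p <- trackPoints(tr)
  idx <- gridCellIndex(land_mask, p$lat, p$lon)
  onland <- !is.na(idx$row) & !is.na(idx$col) &
    land_mask@values[cbind(idx$row, idx$col)] == 1
  if (!any(onland)) return(as.POSIXct(NA, tz = "UTC"))
  p$time[which(onland)[1L]]
}

#' Forecast lead time in days
#'
#' Lead time is the interval between the ensemble initialisation and the
#' parent track's landfall, reported in days to one decimal. When the parent
#' never makes landfall the last fix is used instead, with a warning.
#'
#' @param ens a [TCEnsemble-class].
#' @param land_mask a [LandMask-class].
#' @return numeric lead time in days (1 decimal).
#' @export
leadTimeDays <- function(ens, land_mask) {
  parent <- parentTrack(ens)
  lf <- timeOfLandfall(parent, land_mask)
  if (is.na(lf)) {
    warning("parent track never makes landfall; using last fix as reference")
    p <- trackPoints(parent)
    lf <- p$time[nrow(p)]
  }
  round(as.numeric(difftime(lf, initTime(ens), units = "days")), 1)
}
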