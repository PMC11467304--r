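#' Construct a TC track
#'
#' @param time POSIXct (UTC) fix times, strictly increasing.
#' @param lat,lon numeric fix coordinates, degrees. Longitudes are unwrapped
#'   internally so consecutive fixes never jump by more than 180 degrees.
#' @param p_cen,p_env numeric central / environmental pressure, hPa.
#' @param v_max numeric reported maximum 1-min sustained wind, m/s (NA when
#'   not reported).
#' @param r_max numeric radius of maximum wind, km (NA when not reported).
#' @param member_id integer member id (0 = parent track).
#' @param storm_id character storm identifier.
#' @return A [TCTrack-class] object.
#' @export
tcTrack <- function(time, lat, lon, p_cen, p_env, v_max = NA_real_,
                    r_max = NA_real_, member_id = 0L, storm_id = "STORM") {
  n <- length(time)
  pts <- data.frame(time = as.POSIXct(time, tz = "UTC"),
                    lat = as.numeric(lat),
                    lon = unwrapLon(as.numeric(lon)),
                    p_cen = as.numeric(p_cen),
                    p_env = rep_len(as.numeric(p_env), n),
                    v_max = rep_len(as.numeric(v_max), n),
                    r_max = rep_len(as.numeric(r_max), n))
  step <- if (n >= 2L) diff(as.numeric(pts$time[1:2])) / 3600 else NA_real_
  new("TCTrack", points = pts, member_id = as.integer(member_id),
      storm_id = storm_id, time_step_h = step)
}

#' Construct a forecast ensemble
#'
#' @param members list of [TCTrack-class] objects sharing an init time.
#' @param storm_id character storm identifier.
#' @return A [TCEnsemble-class] object.
#' @export
tcEnsemble <- function(members, storm_id = members[[1L]]@storm_id) {
  init <- members[[1L]]@points$time[1L]
  new("TCEnsemble", members = members, init_time = init, storm_id = storm_id)
}

#' Construct a regular geographic grid
#'
#' @param lon,lat ascending cell-centre coordinate vectors, degrees.
#' @param values numeric matrix `[lat, lon]`.
#' @param res_arcsec grid resolution, arc seconds.
#' @param class_ target class name (a [GeoGrid-class] subclass).
#' @param ... further slots for the subclass.
#' @return A grid object of class `class_`.
#' @export
geoGrid <- function(lon, lat, values, res_arcsec, class_ = "GeoGrid", ...) {
  new(class_, lon = as.numeric(lon), lat = as.numeric(lat),
      values = values, res_arcsec = as.numeric(res_arcsec), ...)
}

#' Construct an impact function
#'
#' Defaults follow the package's calibration convention: the threshold is
#' pinned at the tropical-storm wind speed 25.7 m/s and the asymptote at 1,
#' leaving `v_half` as the free, regionally calibrated parameter.
#'
#' @param v_half wind speed of half saturation, m/s.
#' @param v_thresh wind speed below which impact is zero, m/s.
#' @param scale asymptotic displaced fraction, in (0, 1].
#' @param region_id,event_id optional provenance identifiers.
#' @param usable logical; FALSE marks the zero-impact sentinel.
#' @return An [ImpactFunction-class] object.
#' @export
impactFunction <- function(v_half, v_thresh = 25.7, scale = 1,
                           region_id = NA_character_,
                           event_id = NA_character_, usable = TRUE) {
  new("ImpactFunction", v_thresh = v_thresh, v_half = v_half, scale = scale,
      region_id = as.character(region_id), event_id = as.character(event_id),
      usable = usable)
}

#' Wind model parameter set
#'
#' @param rho_air surface air density, kg/m3.
#' @param b_min,b_max clamp bounds for the Holland shape parameter.
#' @param cutoff_km wind cutoff distance from the track centre, km.
#' @param asym_on add the translational asymmetry component.
#' @param r_max_default fallback radius of maximum wind, km.
#' @param r_max_tiered use the pressure-tiered r_max fallback.
#' @param wind_factor conversion factor applied to reported winds.
#' @return A [WindModelParams-class] object.
#' @export
windModelParams <- function(rho_air = 1.15, b_min = 1.0, b_max = 2.5,
                            cutoff_km = 300, asym_on = TRUE,
                            r_max_default = 40, r_max_tiered = TRUE,
                            wind_factor = 1.0) {
  new("WindModelParams", rho_air = rho_air, b_min = b_min, b_max = b_max,
      cutoff_km = cutoff_km, asym_on = asym_on,
      r_max_default = r_max_default, r_max_tiered = r_max_tiered,
      wind_factor = wind_factor)
}

## ---- accessors --------------------------------------------------------

#' @rdname trackPoints
#' @export
setGeneric("trackPoints", function(x) standardGeneric("trackPoints"))

#' Track and ensemble accessors
#'
#' @param x a [TCTrack-class] or [TCEnsemble-class].
#' @return `trackPoints` the fix data.frame; `memberId` / `stormId` the ids;
#'   `nMembers` the member count; `ensembleMembers` the list of tracks;
#'   `parentTrack` the member with the smallest id; `initTime` the
#'   initialisation time.
#' @aliases trackPoints memberId stormId nMembers ensembleMembers
#'   parentTrack initTime
#' @name trackPoints
NULL

setMethod("trackPoints", "TCTrack", function(x) x@points)

#' @rdname trackPoints
#' @export
setGeneric("memberId", function(x) standardGeneric("memberId"))
setMethod("memberId", "TCTrack", function(x) x@member_id)

#' @rdname trackPoints
#' @export
setGeneric("stormId", function(x) standardGeneric("stormId"))
setMethod("stormId", "TCTrack", function(x) x@storm_id)
setMethod("stormId", "TCEnsemble", function(x) x@storm_id)

#' @rdname trackPoints
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
setMethod("nMembers", "TCEnsemble", function(x) length(x@members))

#' @rdname trackPoints
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))
setMethod("ensembleMembers", "TCEnsemble", function(x) x@members)

#' @rdname trackPoints
#' @export
setGeneric("parentTrack", function(x) standardGeneric("parentTrack"))
setMethod("parentTrack", "TCEnsemble", function(x) {
  ids <- vapply(x@members, memberId, integer(1))
  x@members[[which.min(ids)]]
})

#' @rdname trackPoints
#' @export
setGeneric("initTime", function(x) standardGeneric("initTime"))
setMethod("initTime", "TCEnsemble", function(x) x@init_time)

#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Grid accessors
#'
#' @param x a [GeoGrid-class] (or subclass).
#' @return `gridValues` the `[lat, lon]` value matrix; `gridLons` /
#'   `gridLats` the cell-centre coordinate vectors; `gridResolution` the
#'   resolution in arc seconds; `totalPopulation` the summed person count of
#'   an [ExposureGrid-class].
#' @aliases gridValues gridLons gridLats gridResolution totalPopulation
#' @name gridValues
NULL

setMethod("gridValues", "GeoGrid", function(x) x@values)

#' @rdname gridValues
#' @export
setGeneric("gridLons", function(x) standardGeneric("gridLons"))
setMethod("gridLons", "GeoGrid", function(x) x@lon)

#' @rdname gridValues
#' @export
setGeneric("gridLats", function(x) standardGeneric("gridLats"))
setMethod("gridLats", "GeoGrid", function(x) x@lat)

#' @rdname gridValues
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))
setMethod("gridResolution", "GeoGrid", function(x) x@res_arcsec)

#' @rdname gridValues
#' @export
setGeneric("totalPopulation", function(x) standardGeneric("totalPopulation"))
setMethod("totalPopulation", "ExposureGrid", function(x) sum(x@values))

#' @rdname vHalf
#' @export
setGeneric("vHalf", function(x) standardGeneric("vHalf"))

#' Impact-function and bundle accessors
#'
#' @param x an [ImpactFunction-class] or [FunctionBundle-class].
#' @return `vHalf` / `vThresh` / `impactScale` the curve parameters;
#'   `isUsable` whether the function may enter a bundle;
#'   `bundleMembers` / `bundleBest` the bundle contents.
#' @aliases vHalf vThresh impactScale isUsable bundleMembers bundleBest
#' @name vHalf
NULL

setMethod("vHalf", "ImpactFunction", function(x) x@v_half)

#' @rdname vHalf
#' @export
setGeneric("vThresh", function(x) standardGeneric("vThresh"))
setMethod("vThresh", "ImpactFunction", function(x) x@v_thresh)

#' @rdname vHalf
#' @export
setGeneric("impactScale", function(x) standardGeneric("impactScale"))
setMethod("impactScale", "ImpactFunction", function(x) x@scale)

#' @rdname vHalf
#' @export
setGeneric("isUsable", function(x) standardGeneric("isUsable"))
setMethod("isUsable", "ImpactFunction", function(x) isTRUE(x@usable))

#' @rdname vHalf
#' @export
setGeneric("bundleMembers", function(x) standardGeneric("bundleMembers"))
setMethod("bundleMembers", "FunctionBundle", function(x) x@members)

#' @rdname vHalf
#' @export
setGeneric("bundleBest", function(x) standardGeneric("bundleBest"))
setMethod("bundleBest", "FunctionBundle", function(x) x@best)

## ---- show methods -----------------------------------------------------

setMethod("show", "TCTrack", function(object) {
  p <- object@points
  cat(sprintf("TCTrack %s member %d: %d fixes, %.0f h horizon, step %g h\n",
              object@storm_id, object@member_id, nrow(p),
              diff(range(as.numeric(p$time))) / 3600, object@time_step_h))
  cat(sprintf("  p_cen %.0f-%.0f hPa, lat [%.2f, %.2f], lon [%.2f, %.2f]\n",
              min(p$p_cen), max(p$p_cen), min(p$lat), max(p$lat),
              min(p$lon), max(p$lon)))
})

setMethod("show", "TCEnsemble", function(object) {
  cat(sprintf("TCEnsemble %s: %d members, init %s UTC\n", object@storm_id,
              length(object@members),
              format(object@init_time, "%Y-%m-%d %H:%M")))
})

setMethod("show", "GeoGrid", function(object) {
  cat(sprintf("%s: %d x %d cells at %g arcsec, lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              class(object), length(object@lat), length(object@lon),
              object@res_arcsec, min(object@lon), max(object@lon),
              min(object@lat), max(object@lat)))
  cat(sprintf("  values: sum %.6g, max %.6g\n", sum(object@values),
              max(object@values)))
})

setMethod("show", "ImpactFunction", function(object) {
  cat(sprintf(
    "ImpactFunction: v_thresh %.1f, v_half %.2f m/s, scale %.2f%s%s\n",
    object@v_thresh, object@v_half, object@scale,
    if (!is.na(object@region_id)) paste0(" [", object@region_id, "]") else "",
    if (!object@usable) " (unusable sentinel)" else ""))
})

setMethod("show", "FunctionBundle", function(object) {
  vh <- vapply(object@members, vHalf, numeric(1))
  cat(sprintf("FunctionBundle %s: best v_half %.2f, %d members (v_half %.1f-%.1f)\n",
              object@region_id, object@best@v_half, length(vh),
              min(vh), max(vh)))
})

setMethod("show", "WindModelParams", function(object) {
  cat(sprintf(
    "WindModelParams: rho %.2f, b in [%.1f, %.1f], cutoff %g km, asym %s\n",
    object@rho_air, object@b_min, object@b_max, object@cutoff_km,
    if (object@asym_on) "on" else "off"))
})
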