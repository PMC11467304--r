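#' @import methods
NULL

setOldClass("POSIXct")

#' Tropical cyclone track
#'
#' An ordered sequence of storm fixes for one forecast member. The `points`
#' slot is a data.frame with one row per fix and columns `time` (POSIXct,
#' UTC), `lat` (degrees), `lon` (degrees, unwrapped along the track so
#' consecutive fixes never jump by more than 180), `p_cen` and `p_env`
#' (central and environmental pressure, hPa), `v_max` (reported maximum
#' 1-min sustained wind at 10 m, m/s, may be NA) and `r_max` (radius of
#' maximum wind, km, may be NA).
#'
#' @slot points data.frame of fixes (see description).
#' @slot member_id integer ensemble member id; 0 denotes the parent /
#'   best-estimate track.
#' @slot storm_id character storm identifier.
#' @slot time_step_h numeric native time step between fixes, hours.
#'
#' @exportClass TCTrack
setClass("TCTrack",
  representation(points = "data.frame", member_id = "integer",
                 storm_id = "character", time_step_h = "numeric"))

setValidity("TCTrack", function(object) {
  pts <- object@points
  need <- c("time", "lat", "lon", "p_cen", "p_env", "v_max", "r_max")
  if (!all(need %in% names(pts)))
    return(paste("points must have columns:", paste(need, collapse = ", ")))
  if (nrow(pts) < 2L) return("a track needs at least 2 fixes")
  tt <- as.numeric(pts$time)
  if (any(diff(tt) <= 0)) return("fix times must be strictly increasing")
  if ((tt[length(tt)] - tt[1L]) > 240 * 3600 + 1e-6)
    return("track horizon exceeds 240 h")
  if (any(pts$lat < -90 | pts$lat > 90)) return("latitude outside [-90, 90]")
  if (any(!is.finite(pts$p_cen)) || any(!is.finite(pts$p_env)))
    return("pressures must be finite")
  if (any(pts$p_cen <= 0)) return("central pressure must be positive")
  if (any(pts$p_env < pts$p_cen))
    return("environmental pressure below central pressure")
  if (any(pts$v_max < 0, na.rm = TRUE)) return("negative reported wind")
  if (any(abs(diff(pts$lon)) > 180))
    return("longitudes not unwrapped (consecutive jump > 180 degrees)")
  if (length(object@member_id) != 1L || is.na(object@member_id) ||
      object@member_id < 0L)
    return("member_id must be a single non-negative integer")
  TRUE
})

#' Forecast ensemble of TC tracks
#'
#' A set of tracks issued at the same initialisation time, typically the 51
#' perturbed members of a numerical-weather-prediction ensemble.
#'
#' @slot members list of [TCTrack-class] objects.
#' @slot init_time POSIXct forecast initialisation time (UTC).
#' @slot storm_id character storm identifier.
#'
#' @exportClass TCEnsemble
setClass("TCEnsemble",
  representation(members = "list", init_time = "POSIXct",
                 storm_id = "character"))

setValidity("TCEnsemble", function(object) {
  if (length(object@members) < 1L) return("ensemble needs >= 1 member")
  ok <- vapply(object@members, function(m) is(m, "TCTrack"), logical(1))
  if (!all(ok)) return("all members must be TCTrack objects")
  ids <- vapply(object@members, function(m) m@member_id, integer(1))
  if (anyDuplicated(ids)) return("member ids must be unique")
  t0 <- vapply(object@members,
               function(m) as.numeric(m@points$time[1L]), numeric(1))
  if (any(abs(t0 - as.numeric(object@init_time)) > 1e-6))
    return("all members must start at the ensemble init_time")
  TRUE
})

#' Regular geographic grid
#'
#' A regular WGS84 lat/lon grid of cell-centre values. `lat` and `lon` are
#' ascending cell-centre coordinate vectors; `values` is a matrix with
#' `length(lat)` rows and `length(lon)` columns. Cell extents are half-open
#' `[west, east) x [south, north)` around each centre.
#'
#' @slot lon numeric ascending cell-centre longitudes, degrees in
#'   `[-180, 180)`.
#' @slot lat numeric ascending cell-centre latitudes, degrees.
#' @slot values numeric matrix `[lat, lon]` of cell values.
#' @slot res_arcsec numeric grid resolution in arc seconds.
#'
#' @exportClass GeoGrid
setClass("GeoGrid",
  representation(lon = "numeric", lat = "numeric", values = "matrix",
                 res_arcsec = "numeric"))

setValidity("GeoGrid", function(object) {
  if (nrow(object@values) != length(object@lat) ||
      ncol(object@values) != length(object@lon))
    return("values matrix must be [length(lat) x length(lon)]")
  reg <- function(x) length(x) < 3L || max(abs(diff(diff(x)))) < 1e-8
  if (!reg(object@lon) || !reg(object@lat))
    return("grid spacing must be regular")
  if (length(object@lon) > 1L && any(diff(object@lon) <= 0))
    return("longitudes must be ascending")
  if (length(object@lat) > 1L && any(diff(object@lat) <= 0))
    return("latitudes must be ascending")
  if (length(object@res_arcsec) != 1L || object@res_arcsec <= 0)
    return("res_arcsec must be a positive scalar")
  TRUE
})

#' Gridded population exposure
#'
#' A [GeoGrid-class] whose values are person counts per cell.
#'
#' @exportClass ExposureGrid
setClass("ExposureGrid", contains = "GeoGrid")

setValidity("ExposureGrid", function(object) {
  if (any(!is.finite(object@values))) return("population must be finite")
  if (any(object@values < 0)) return("population must be non-negative")
  TRUE
})

#' Wind hazard field
#'
#' A [GeoGrid-class] of the lifetime-maximum 1-min sustained wind at 10 m
#' (m/s) experienced at each cell during one ensemble member's track.
#'
#' @slot storm_id character storm identifier.
#' @slot member_id integer ensemble member the field belongs to.
#'
#' @exportClass HazardField
setClass("HazardField", contains = "GeoGrid",
  representation(storm_id = "character", member_id = "integer"))

setValidity("HazardField", function(object) {
  if (any(object@values < 0)) return("wind speeds must be non-negative")
  TRUE
})

#' Land mask
#'
#' A [GeoGrid-class] of 0/1 values; 1 marks a land cell.
#'
#' @exportClass LandMask
setClass("LandMask", contains = "GeoGrid")

setValidity("LandMask", function(object) {
  if (!all(object@values %in% c(0, 1))) return("mask values must be 0 or 1")
  TRUE
})

#' Sigmoid impact (vulnerability) function
#'
#' Third-order sigmoid mapping wind speed to the fraction of exposed people
#' displaced: `f(V) = scale * x^3 / (1 + x^3)` with
#' `x = max(V - v_thresh, 0) / (v_half - v_thresh)`.
#'
#' @slot v_thresh numeric wind speed (m/s) below which impact is zero.
#' @slot v_half numeric wind speed (m/s) of half saturation.
#' @slot scale numeric asymptotic displaced fraction, in (0, 1].
#' @slot region_id character calibration region (may be NA).
#' @slot event_id character event the function was fitted to (may be NA);
#'   used for deterministic tie-breaking when bundles are ranked.
#' @slot usable logical; FALSE flags the sentinel returned when an event
#'   reports zero displacement (excluded from bundles).
#'
#' @exportClass ImpactFunction
setClass("ImpactFunction",
  representation(v_thresh = "numeric", v_half = "numeric", scale = "numeric",
                 region_id = "character", event_id = "character",
                 usable = "logical"))

setValidity("ImpactFunction", function(object) {
  if (object@v_thresh < 0) return("v_thresh must be >= 0")
  if (object@v_half <= object@v_thresh) return("v_half must exceed v_thresh")
  if (object@scale <= 0 || object@scale > 1) return("scale must be in (0, 1]")
  TRUE
})

#' Bundle of impact functions for one region
#'
#' The regional best-estimate function together with the per-event functions
#' retained inside the central 80% band of fitted `v_half` values; the
#' bundle is the discrete vulnerability uncertainty distribution used by the
#' sensitivity analysis.
#'
#' @slot region_id character region identifier.
#' @slot best [ImpactFunction-class] regional RMSF optimum.
#' @slot members list of retained per-event [ImpactFunction-class] objects.
#'
#' @exportClass FunctionBundle
setClass("FunctionBundle",
  representation(region_id = "character", best = "ImpactFunction",
                 members = "list"))

setValidity("FunctionBundle", function(object) {
  if (length(object@members) < 1L) return("bundle must be non-empty")
  ok <- vapply(object@members, function(f)
    is(f, "ImpactFunction") && isTRUE(validObject(f, test = TRUE)),
    logical(1))
  if (!all(ok)) return("all bundle members must be valid ImpactFunctions")
  TRUE
})

#' Parameters of the parametric wind model
#'
#' @slot rho_air numeric surface air density, kg/m3.
#' @slot b_min,b_max numeric clamp bounds for the Holland shape parameter.
#' @slot cutoff_km numeric maximum distance (km) from the track centre with
#'   non-zero wind.
#' @slot asym_on logical add the translational asymmetry component.
#' @slot r_max_default numeric fallback radius of maximum wind (km) when a
#'   fix carries none and the pressure-tiered table is disabled.
#' @slot r_max_tiered logical use the pressure-tiered r_max fallback
#'   (dp < 25 hPa -> 50 km, 25-50 -> 40 km, > 50 -> 30 km).
#' @slot wind_factor numeric multiplicative conversion applied to reported
#'   winds (1.0 for 1-min sustained inputs; 1/0.88 converts 10-min means).
#'
#' @exportClass WindModelParams
setClass("WindModelParams",
  representation(rho_air = "numeric", b_min = "numeric", b_max = "numeric",
                 cutoff_km = "numeric", asym_on = "logical",
                 r_max_default = "numeric", r_max_tiered = "logical",
                 wind_factor = "numeric"),
  prototype(rho_air = 1.15, b_min = 1.0, b_max = 2.5, cutoff_km = 300,
            asym_on = TRUE, r_max_default = 40, r_max_tiered = TRUE,
            wind_factor = 1.0))

setValidity("WindModelParams", function(object) {
  if (object@rho_air <= 0) return("rho_air must be positive")
  if (object@b_min >= object@b_max) return("b_min must be below b_max")
  if (object@cutoff_km <= 0) return("cutoff_km must be positive")
  if (object@wind_factor <= 0) return("wind_factor must be positive")
  TRUE
})
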