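#' Displaced fraction at a given wind speed
#'
#' Evaluates the third-order sigmoid impact function
#' `scale * x^3 / (1 + x^3)` with
#' `x = max(V - v_thresh, 0) / (v_half - v_thresh)`. Exactly zero for
#' `V <= v_thresh`; `scale / 2` at `V = v_half`; approaches `scale` as `V`
#' grows.
#'
#' @param f an [ImpactFunction-class].
#' @param V wind speed(s), m/s.
#' @return numeric displaced fraction(s) in `[0, scale)`.
#' @export
displacedFraction <- function(f, V) {
  stopIfNot(all(V >= 0, na.rm = TRUE), "wind speed must be non-negative")
  x <- pmax(V - f@v_thresh, 0) / (f@v_half - f@v_thresh)
  f@scale * x^3 / (1 + x^3)
}

#' Root-mean-square fraction (RMSF) error
#'
#' `exp(sqrt(mean(log(m_i / o_i)^2)))` over events: 1 for perfect
#' predictions, 2 for a uniform factor-2 bias in either direction. Both
#' modeled and observed totals are floored at one person so zero-impact
#' events keep the measure finite.
#'
#' @param modeled,observed numeric vectors of per-event person totals.
#' @return dimensionless RMSF >= 1.
#' @export
rmsf <- function(modeled, observed) {
  stopIfNot(length(modeled) == length(observed), "length mismatch")
  stopIfNot(length(modeled) > 0, "empty input")
  m <- pmax(modeled, 1)
  o <- pmax(observed, 1)
  exp(sqrt(mean(log(m / o)^2)))
}

#' Build a displacement event record
#'
#' Couples a reported displacement total with the wind hazard footprint of
#' the event's historical track on a shared exposure grid.
#'
#' @param event_id character event identifier.
#' @param region_id character calibration region.
#' @param reported reported displaced persons (>= 0).
#' @param hazard a [HazardField-class] on the calibration exposure grid.
#' @return list of class `tcEvent`.
#' @export
eventRecord <- function(event_id, region_id, reported, hazard) {
  stopIfNot(reported >= 0, "reported displacement must be non-negative")
  structure(list(event_id = event_id, region_id = region_id,
                 reported = reported, hazard = hazard),
            class = "tcEvent")
}

# modeled displacement total of one event for a candidate v_half
modeledTotal <- function(event, exposure, v_half, v_thresh, scale) {
  f <- impactFunction(v_half, v_thresh = v_thresh, scale = scale)
  sum(exposure@values * displacedFraction(f, event$hazard@values))
}

#' Calibrate an impact function for one event
#'
#' Finds the `v_half` at which the modeled displacement total equals the
#' reported total (the squared-error optimum). The modeled total is strictly
#' decreasing in `v_half`, so a deterministic bracketed root search is used;
#' when the reported value is unattainable within the bounds the estimate is
#' clamped at the corresponding bound.
#'
#' @param event a `tcEvent` (see [eventRecord()]).
#' @param exposure the calibration [ExposureGrid-class].
#' @param bounds numeric length-2 search bounds on `v_half`, m/s.
#' @param v_thresh,scale fixed curve parameters.
#' @param tol search tolerance on `v_half`, m/s.
#' @return An [ImpactFunction-class]; events reporting zero displacement get
#'   an unusable sentinel (see [isUsable()]).
#' @export
calibrateEvent <- function(event, exposure, bounds = c(25.8, 150),
                           v_thresh = 25.7, scale = 1, tol = 0.01) {
  if (event$reported <= 0)
    return(impactFunction(bounds[2L], v_thresh = v_thresh, scale = scale,
                          region_id = event$region_id,
                          event_id = event$event_id, usable = FALSE))
  g <- function(vh) modeledTotal(event, exposure, vh, v_thresh, scale) -
    event$reported
  glo <- g(bounds[1L]); ghi <- g(bounds[2L])
  vh <- if (glo <= 0) bounds[1L]       # reported above what wind can displace
  else if (ghi >= 0) bounds[2L]        # reported below the flattest curve
  else stats::uniroot(g, bounds, tol = tol)$root
  impactFunction(vh, v_thresh = v_thresh, scale = scale,
                 region_id = event$region_id, event_id = event$event_id)
}

#' Calibrate the regional impact function by RMSF minimisation
#'
#' One `v_half` per region, minimising the [rmsf()] error of modeled versus
#' reported displacement over all of the region's events, via deterministic
#' bounded scalar search.
#'
#' @param events list of `tcEvent` records (see [eventRecord()]).
#' @param exposure the calibration [ExposureGrid-class].
#' @param bounds,v_thresh,scale,tol as in [calibrateEvent()].
#' @return An [ImpactFunction-class] with attribute `rmsf`, the achieved
#'   RMSF at the optimum.
#' @export
calibrateRegion <- function(events, exposure, bounds = c(25.8, 150),
                            v_thresh = 25.7, scale = 1, tol = 0.01) {
  stopIfNot(length(events) > 0, "no events")
  reported <- vapply(events, function(e) e$reported, numeric(1))
  stopIfNot(any(reported > 0), "all reported impacts are zero")
  obj <- function(vh) {
    m <- vapply(events, function(e)
      modeledTotal(e, exposure, vh, v_thresh, scale), numeric(1))
    rmsf(m, reported)
  }
  opt <- stats::optimize(obj, bounds, tol = tol)
  out <- impactFunction(opt$minimum, v_thresh = v_thresh, scale = scale,
                        region_id = events[[1L]]$region_id)
  attr(out, "rmsf") <- opt$objective
  out
}

#' Select the central bundle of per-event impact functions
#'
#' Ranks the usable per-event functions by `v_half` (ties broken by
#' event id) and retains those inside the central `q` band of the empirical
#' distribution, i.e. between the `(1-q)/2` and `(1+q)/2` rank quantiles.
#'
#' @param funcs list of per-event [ImpactFunction-class] objects.
#' @param best the regional best-estimate [ImpactFunction-class].
#' @param q central probability mass retained (default 0.80).
#' @param region_id character region label for the bundle.
#' @return A [FunctionBundle-class].
#' @export
selectBundle <- function(funcs, best, q = 0.80,
                         region_id = best@region_id) {
  funcs <- Filter(isUsable, funcs)
  stopIfNot(length(funcs) >= 3L, "need >= 3 usable per-event functions")
  vh <- vapply(funcs, vHalf, numeric(1))
  eid <- vapply(funcs, function(f) f@event_id, character(1))
  ord <- order(vh, eid)
  n <- length(ord)
  drop <- floor(n * (1 - q) / 2 + 1e-9)
  keep <- ord[seq.int(drop + 1L, n - drop)]
  new("FunctionBundle", region_id = as.character(region_id), best = best,
      members = funcs[keep])
}

#' Write / read impact functions as JSON
#'
#' @param x an [ImpactFunction-class] or [FunctionBundle-class].
#' @param path file path.
#' @return `path` invisibly (write); the reconstructed object (read).
#' @export
writeImpactFunctions <- function(x, path) {
  asRec <- function(f) list(region_id = f@region_id, event_id = f@event_id,
                            v_thresh = f@v_thresh, v_half = f@v_half,
                            scale = f@scale)
  obj <- if (is(x, "FunctionBundle"))
    list(region_id = x@region_id, best = asRec(x@best),
         members = lapply(x@members, asRec))
  else asRec(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImpactFunctions
#' @export
readImpactFunctions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  asFun <- function(r) impactFunction(
    r$v_half, v_thresh = r$v_thresh, scale = r$scale,
    region_id = r$region_id %||% NA_character_,
    event_id = r$event_id %||% NA_character_)
  if (!is.null(obj$members))
    new("FunctionBundle", region_id = obj$region_id, best = asFun(obj$best),
        members = lapply(obj$members, asFun))
  else asFun(obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
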