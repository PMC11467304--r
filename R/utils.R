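# internal geometry helpers; all distances use a spherical Earth, R = 6371 km

EARTH_RADIUS_M <- 6371000

# unwrap a longitude sequence so consecutive values never jump by > 180
unwrapLon <- function(lon) {
  if (length(lon) < 2L) return(lon)
  lon + cumsum(c(0, -360 * round(diff(lon) / 360)))
}

# normalise longitudes to [-180, 180)
normLon <- function(lon) ((lon + 180) %% 360) - 180

# normalise the longitude column of a point / point matrix (grids that
# straddle the antimeridian carry longitudes outside [-180, 180))
normPts <- function(p) {
  if (is.matrix(p)) p[, 1L] <- normLon(p[, 1L]) else p[1L] <- normLon(p[1L])
  p
}

# great-circle distance (km); p1 is c(lon, lat) or matrix, p2 likewise
haversineKm <- function(p1, p2) {
  geosphere::distHaversine(normPts(p1), normPts(p2), r = EARTH_RADIUS_M) / 1000
}

# initial great-circle bearing in degrees [0, 360)
bearingDeg <- function(p1, p2) {
  b <- geosphere::bearing(normPts(p1), normPts(p2))
  (b + 360) %% 360
}

# locate points in a regular grid; returns row (lat) / col (lon) indices or
# NA when outside; half-open cell extents [west, east) x [south, north)
gridCellIndex <- function(grid, lat, lon) {
  res <- grid@res_arcsec / 3600
  # longitude offset modulo 360 so queries match grids that straddle the
  # antimeridian regardless of wrapping convention
  dlon <- (lon - (grid@lon[1L] - res / 2)) %% 360
  col <- floor(dlon / res) + 1L
  row <- floor((lat - (grid@lat[1L] - res / 2)) / res) + 1L
  col[col < 1L | col > length(grid@lon)] <- NA_integer_
  row[row < 1L | row > length(grid@lat)] <- NA_integer_
  list(row = row, col = col)
}

# matrix of all cell centres, columns (lon, lat), in values-vector order
# (column-major over the [lat, lon] matrix)
gridCentres <- function(grid) {
  cbind(lon = rep(grid@lon, each = length(grid@lat)),
        lat = rep(grid@lat, times = length(grid@lon)))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# evaluate expr under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
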