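# ESRI ASCII grid reader shared by population and land-mask layers
readGridAscii <- function(path) {
  stopIfNot(file.exists(path), paste("no such raster file:", path))
  lines <- readLines(path)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      nhdr <- nhdr + 1L
    } else break
  }
  stopIfNot(all(c("ncols", "nrows", "cellsize") %in% names(hdr)),
            "ASCII grid header must define ncols, nrows, cellsize")
  vals <- scan(text = lines[-seq_len(nhdr)], quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows; res <- hdr$cellsize
  stopIfNot(length(vals) == nc * nr, "ASCII grid data size mismatch")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- 0
  # file rows run north to south; flip into ascending-latitude order
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  x0 <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + res / 2
  y0 <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + res / 2
  list(lon = x0 + (seq_len(nc) - 1L) * res,
       lat = y0 + (seq_len(nr) - 1L) * res,
       values = m, res_arcsec = res * 3600)
}

# writer mirroring readGridAscii (cell-centre registration preserved)
writeGridAscii <- function(grid, path, nodata = -9999) {
  res <- grid@res_arcsec / 3600
  hdr <- c(sprintf("ncols %d", length(grid@lon)),
           sprintf("nrows %d", length(grid@lat)),
           sprintf("xllcorner %.10g", grid@lon[1L] - res / 2),
           sprintf("yllcorner %.10g", grid@lat[1L] - res / 2),
           sprintf("cellsize %.10g", res),
           sprintf("NODATA_value %d", nodata))
  m <- grid@values[rev(seq_along(grid@lat)), , drop = FALSE]
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gridded population layer
#'
#' Reads an ESRI ASCII grid (WGS84, cell values = person counts). Nodata
#' cells are mapped to 0 so they participate in all sums.
#'
#' @param path path to the `.asc` file.
#' @return An [ExposureGrid-class].
#' @export
readPopulation <- function(path) {
  g <- readGridAscii(path)
  stopIfNot(all(g$values >= 0), "population raster contains negative cells")
  geoGrid(g$lon, g$lat, g$values, g$res_arcsec, class_ = "ExposureGrid")
}

#' Write a population layer
#'
#' @param exp an [ExposureGrid-class].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
writePopulation <- function(exp, path) writeGridAscii(exp, path)

#' Read a land mask
#'
#' @param path path to an ESRI ASCII grid of 0/1 values.
#' @return A [LandMask-class].
#' @export
readLandMask <- function(path) {
  g <- readGridAscii(path)
  geoGrid(g$lon, g$lat, g$values, g$res_arcsec, class_ = "LandMask")
}

#' Crop an exposure grid to the neighbourhood of an ensemble
#'
#' Retains the bounding box of cells lying within `buffer_km` of any member
#' fix; the buffer should be at least the wind model's cutoff distance so no
#' impacted cell is dropped.
#'
#' @param exp an [ExposureGrid-class].
#' @param ens a [TCEnsemble-class].
#' @param buffer_km buffer distance, km.
#' @return The cropped [ExposureGrid-class]; an empty grid (with a warning)
#'   when no cell lies within the buffer.
#' @export
cropToTrack <- function(exp, ens, buffer_km = 300) {
  fixes <- do.call(rbind, lapply(ensembleMembers(ens), function(tr) {
    p <- trackPoints(tr)
    cbind(normLon(p$lon), p$lat)
  }))
  dlat <- buffer_km / 111.195
  latok <- exp@lat >= min(fixes[, 2L]) - dlat &
    exp@lat <= max(fixes[, 2L]) + dlat
  dlon <- buffer_km / (111.195 * max(cos(mean(fixes[, 2L]) * pi / 180), 0.05))
  dl <- abs(normLon(outer(exp@lon, fixes[, 1L], "-")))
  lonok <- apply(dl <= dlon, 1L, any)
  if (!any(latok) || !any(lonok)) {
    warning("no exposure cells within buffer of the ensemble; empty grid")
    return(geoGrid(numeric(0), numeric(0),
                   matrix(numeric(0), 0, 0), exp@res_arcsec,
                   class_ = "ExposureGrid"))
  }
  ri <- range(which(latok)); ci <- range(which(lonok))
  geoGrid(exp@lon[ci[1L]:ci[2L]], exp@lat[ri[1L]:ri[2L]],
          exp@values[ri[1L]:ri[2L], ci[1L]:ci[2L], drop = FALSE],
          exp@res_arcsec, class_ = "ExposureGrid")
}

#' Scale the total population homogeneously
#'
#' Every cell is multiplied by `factor`; the spatial pattern is unchanged.
#' This is the exposure uncertainty model: only the total is uncertain.
#'
#' @param exp an [ExposureGrid-class].
#' @param factor positive scaling factor.
#' @return The scaled [ExposureGrid-class].
#' @export
scaleTotal <- function(exp, factor) {
  stopIfNot(is.numeric(factor) && length(factor) == 1L && factor > 0,
            "factor must be a positive scalar")
  geoGrid(exp@lon, exp@lat, exp@values * factor, exp@res_arcsec,
          class_ = "ExposureGrid")
}
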