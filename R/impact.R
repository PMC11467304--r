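#' Spatially explicit displacement impact of one hazard field
#'
#' Per cell `I_j = E_j * f(V_j)`; the total is the sum over cells. Impacts
#' are expected values in real-valued persons (no rounding).
#'
#' @param hazard a [HazardField-class].
#' @param exp an [ExposureGrid-class] on the same cell centres.
#' @param f an [ImpactFunction-class].
#' @return list of class `impactResult` with elements `member_id`,
#'   `per_cell` (matrix `[lat, lon]`, persons) and `total` (persons).
#' @export
computeImpact <- function(hazard, exp, f) {
  stopIfNot(length(hazard@lon) == length(exp@lon) &&
              length(hazard@lat) == length(exp@lat) &&
              max(abs(hazard@lon - exp@lon), 0) < 1e-9 &&
              max(abs(hazard@lat - exp@lat), 0) < 1e-9,
            "hazard and exposure grids are not aligned")
  per_cell <- exp@values * displacedFraction(f, hazard@values)
  structure(list(member_id = hazard@member_id, per_cell = per_cell,
                 total = sum(per_cell)),
            class = "impactResult")
}

#' Per-member forecast impact distribution
#'
#' Computes one wind field and impact per ensemble member with fixed
#' exposure and impact function, i.e. the forecast distribution under
#' meteorological uncertainty alone.
#'
#' @param ens a [TCEnsemble-class].
#' @param exp an [ExposureGrid-class].
#' @param f an [ImpactFunction-class].
#' @param params a [WindModelParams-class].
#' @param hazards optional pre-computed list of [HazardField-class], one per
#'   member (skips the wind computation).
#' @return list of class `impactDistribution` with `member_ids`, `totals`,
#'   `mean`, `min`, `max`, `zero_fraction`, `mean_map` (a [GeoGrid-class] of
#'   per-cell means over members) and `hazards` (the member hazard fields).
#' @export
ensembleImpacts <- function(ens, exp, f, params = windModelParams(),
                            hazards = NULL) {
  stopIfNot(nMembers(ens) >= 1, "empty ensemble")
  members <- ensembleMembers(ens)
  if (is.null(hazards))
    hazards <- lapply(members, computeWindfield, grid = exp, params = params)
  acc <- matrix(0, length(exp@lat), length(exp@lon))
  totals <- numeric(length(members))
  for (i in seq_along(members)) {
    res <- computeImpact(hazards[[i]], exp, f)
    totals[i] <- res$total
    acc <- acc + res$per_cell
  }
  mean_map <- geoGrid(exp@lon, exp@lat, acc / length(members),
                      exp@res_arcsec)
  structure(list(member_ids = vapply(members, memberId, integer(1)),
                 totals = totals, mean = mean(totals), min = min(totals),
                 max = max(totals), zero_fraction = mean(totals == 0),
                 mean_map = mean_map, hazards = hazards),
            class = "impactDistribution")
}

#' Summarise a forecast impact distribution
#'
#' @param dist an `impactDistribution` (see [ensembleImpacts()]) or a bare
#'   numeric vector of member totals.
#' @param percentiles numeric percentiles (0-100) to report.
#' @return one-row data.frame with mean, min, max, the requested percentiles
#'   (columns `p<q>`) and the zero-impact member fraction.
#' @export
summarizeImpacts <- function(dist, percentiles = c(5, 25, 50, 75, 95)) {
  totals <- if (is.numeric(dist)) dist else dist$totals
  stopIfNot(length(totals) > 0, "no member totals")
  qs <- stats::quantile(totals, percentiles / 100, names = FALSE, type = 7)
  out <- data.frame(n_members = length(totals), mean = mean(totals),
                    min = min(totals), max = max(totals),
                    zero_fraction = mean(totals == 0))
  for (i in seq_along(percentiles))
    out[[paste0("p", percentiles[i])]] <- qs[i]
  out
}
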