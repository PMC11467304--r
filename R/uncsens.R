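#' Evaluate the impact model over a Saltelli design
#'
#' Runs the displacement model at every design row. Because the total impact
#' is exactly linear in the exposure scaling, the per-(member, function)
#' impact totals are computed once and each run is the cached total times
#' its scale factor; results are identical to naive re-evaluation.
#'
#' @param design a `saltelliDesign` from [buildDesign()].
#' @param ens a [TCEnsemble-class] with `design$space$n_members` members.
#' @param exp an [ExposureGrid-class].
#' @param bundle a [FunctionBundle-class] with `design$space$bundle_size`
#'   members.
#' @param params a [WindModelParams-class].
#' @param hazards optional pre-computed member hazard fields.
#' @param naive logical; re-evaluate every run from scratch (slow; used as
#'   a cross-check oracle).
#' @return list with outputs `fA`, `fB` (length `base_n`), `fAB`
#'   (`base_n x 3`), all run totals `totals` (length `total_runs`, ordered
#'   A, B, AB_1..AB_3), the cached member hazard fields, and the
#'   per-(member, function) total matrix `cache`.
#' @export
runSamples <- function(design, ens, exp, bundle, params = windModelParams(),
                       hazards = NULL, naive = FALSE) {
  space <- design$space
  members <- ensembleMembers(ens)
  funcs <- bundleMembers(bundle)
  stopIfNot(length(members) == space$n_members,
            "ensemble size does not match the design input space")
  stopIfNot(length(funcs) == space$bundle_size,
            "bundle size does not match the design input space")
  if (is.null(hazards))
    hazards <- lapply(members, computeWindfield, grid = exp, params = params)
  evalRows <- function(U) {
    mu <- mapUnits(U, space)
    if (naive) {
      vapply(seq_len(nrow(mu)), function(r) {
        scaled <- scaleTotal(exp, mu$scale[r])
        computeImpact(hazards[[mu$member[r] + 1L]], scaled,
                      funcs[[mu$fun[r] + 1L]])$total
      }, numeric(1))
    } else {
      key <- cbind(mu$member + 1L, mu$fun + 1L)
      mu$scale * cache[key]
    }
  }
  cache <- NULL
  if (!naive) {
    cache <- matrix(NA_real_, length(members), length(funcs))
    for (m in seq_along(members))
      for (f in seq_along(funcs))
        cache[m, f] <- computeImpact(hazards[[m]], exp, funcs[[f]])$total
  }
  fA <- evalRows(design$A)
  fB <- evalRows(design$B)
  fAB <- vapply(seq_len(dim(design$AB)[3L]),
                function(i) evalRows(design$AB[, , i]),
                numeric(design$base_n))
  list(fA = fA, fB = fB, fAB = fAB, totals = c(fA, fB, as.vector(fAB)),
       hazards = hazards, cache = cache)
}

#' Global uncertainty and sensitivity analysis of one forecast
#'
#' Convenience wrapper: builds the Saltelli design over (ensemble member,
#' exposure scaling, impact function), evaluates all runs, and estimates
#' first-order Sobol indices with bootstrap confidence intervals.
#'
#' @param ens a [TCEnsemble-class].
#' @param exp an [ExposureGrid-class].
#' @param bundle a [FunctionBundle-class].
#' @param params a [WindModelParams-class].
#' @param scale_range exposure scaling range (default `[0.8, 1.2]`).
#' @param base_n Saltelli base sample count (power of two; the model is run
#'   `base_n * 5` times).
#' @param seed integer seed (Sobol scrambling and bootstrap).
#' @param n_boot bootstrap resamples for the index confidence intervals.
#' @param hazards optional pre-computed member hazard fields.
#' @return list with `indices` (a `sensitivityResult`), `samples` (the run
#'   evaluation from [runSamples()]), `design`, `mean`, `variance` and the
#'   full vector of run `totals`.
#' @export
uncertaintyAnalysis <- function(ens, exp, bundle, params = windModelParams(),
                                scale_range = c(0.8, 1.2), base_n = 2048,
                                seed = 42, n_boot = 1000, hazards = NULL) {
  if (length(bundleMembers(bundle)) < 2L)
    warning("bundle has a single function; the vulnerability input is inert")
  design <- buildDesign(n_members = nMembers(ens),
                        bundle_size = length(bundleMembers(bundle)),
                        scale_range = scale_range, base_n = base_n,
                        seed = seed)
  samples <- runSamples(design, ens, exp, bundle, params, hazards = hazards)
  indices <- sobolFirstOrder(samples$fA, samples$fB, samples$fAB,
                             inputs = design$inputs, n_boot = n_boot,
                             seed = seed)
  list(indices = indices, samples = samples, design = design,
       mean = mean(samples$totals), variance = stats::var(samples$totals),
       totals = samples$totals)
}

#' Dominant uncertain input per grid cell
#'
#' Computes per-cell first-order Sobol indices in blocks of cells (bounding
#' memory) and reports, for each cell, which input explains the most output
#' variance. Cells whose impact variance across runs is below `var_tol` are
#' flagged 0 ("none"); otherwise codes are 1 = member, 2 = scale,
#' 3 = function (negative index estimates are clipped to 0 for the argmax).
#'
#' @param design a `saltelliDesign`.
#' @param ens,exp,bundle,params as in [runSamples()].
#' @param hazards optional pre-computed member hazard fields.
#' @param var_tol variance tolerance (persons^2) below which a cell has no
#'   dominant input.
#' @param block number of cells processed per pass.
#' @return A [GeoGrid-class] of integer codes with attribute `legend`.
#' @export
perCellDominant <- function(design, ens, exp, bundle,
                            params = windModelParams(), hazards = NULL,
                            var_tol = 1e-12, block = 512L) {
  space <- design$space
  members <- ensembleMembers(ens)
  funcs <- bundleMembers(bundle)
  if (is.null(hazards))
    hazards <- lapply(members, computeWindfield, grid = exp, params = params)
  M <- length(members); FN <- length(funcs)
  muA <- mapUnits(design$A, space)
  muB <- mapUnits(design$B, space)
  muAB <- lapply(seq_len(3L), function(i) mapUnits(design$AB[, , i], space))
  rowKey <- function(mu) (mu$fun) * M + mu$member + 1L
  kA <- rowKey(muA); kB <- rowKey(muB); kAB <- lapply(muAB, rowKey)
  hazmat <- vapply(hazards, function(h) as.vector(h@values),
                   numeric(length(exp@values)))   # cells x members
  pop <- as.vector(exp@values)
  ncell <- length(pop)
  code <- integer(ncell)
  thr_min <- min(vapply(funcs, vThresh, numeric(1)))
  for (start in seq(1L, ncell, by = block)) {
    cells <- start:min(start + block - 1L, ncell)
    hz <- hazmat[cells, , drop = FALSE]
    if (all(hz <= thr_min) || all(pop[cells] == 0)) next
    # impacts per (member, function) for this cell block: (M*FN) x nb
    IM <- matrix(0, M * FN, length(cells))
    for (f in seq_len(FN)) {
      frac <- displacedFraction(funcs[[f]], hz)      # nb x M
      IM[(f - 1L) * M + seq_len(M), ] <- t(frac * pop[cells])
    }
    if (all(IM == 0)) next
    fA <- IM[kA, , drop = FALSE] * muA$scale
    fB <- IM[kB, , drop = FALSE] * muB$scale
    y <- rbind(fA, fB)
    v <- colMeans(y^2) - colMeans(y)^2
    v <- v * nrow(y) / (nrow(y) - 1L)
    Smax <- matrix(-Inf, 3L, length(cells))
    for (i in seq_len(3L)) {
      fABi <- IM[kAB[[i]], , drop = FALSE] * muAB[[i]]$scale
      Smax[i, ] <- colMeans(fB * (fABi - fA)) / pmax(v, var_tol)
    }
    Smax[Smax < 0] <- 0
    dom <- apply(Smax, 2L, which.max)
    dom[v < var_tol] <- 0L
    code[cells] <- dom
  }
  out <- geoGrid(exp@lon, exp@lat,
                 matrix(code, length(exp@lat), length(exp@lon)),
                 exp@res_arcsec)
  attr(out, "legend") <- c("0" = "none", "1" = "member", "2" = "scale",
                           "3" = "function")
  out
}

#' Uncertainty and sensitivity analysis across forecast lead times
#'
#' Repeats [uncertaintyAnalysis()] for ensembles issued at successive
#' initialisation times; lead times are measured from each initialisation to
#' the parent track's landfall on the supplied mask.
#'
#' @param ensembles list of [TCEnsemble-class] objects (successive init
#'   times).
#' @param exp an [ExposureGrid-class].
#' @param bundle a [FunctionBundle-class].
#' @param land_mask a [LandMask-class] used for the landfall time.
#' @param params a [WindModelParams-class].
#' @param base_n,seed,n_boot,scale_range forwarded to
#'   [uncertaintyAnalysis()].
#' @return list with `table` (one row per input per lead time: `input`,
#'   `S1`, `ci_low`, `ci_high`, `lead_time_days`, `mean`, `sd`) and `runs`
#'   (per lead time, the full analysis object), both ordered by decreasing
#'   lead time.
#' @export
leadTimeSweep <- function(ensembles, exp, bundle, land_mask,
                          params = windModelParams(), base_n = 512,
                          seed = 42, n_boot = 200,
                          scale_range = c(0.8, 1.2)) {
  stopIfNot(length(ensembles) >= 1, "need at least one ensemble")
  leads <- vapply(ensembles, leadTimeDays, numeric(1),
                  land_mask = land_mask)
  ord <- order(leads, decreasing = TRUE)
  runs <- list()
  rows <- list()
  for (k in ord) {
    ua <- uncertaintyAnalysis(ensembles[[k]], exp, bundle, params,
                              scale_range = scale_range, base_n = base_n,
                              seed = seed, n_boot = n_boot)
    tab <- ua$indices
    tab$lead_time_days <- leads[k]
    tab$mean <- ua$mean
    tab$sd <- stats::sd(ua$totals)
    rows[[length(rows) + 1L]] <- tab
    runs[[sprintf("%.1f", leads[k])]] <- ua
  }
  list(table = do.call(rbind, rows), runs = runs,
       lead_time_days = sort(leads, decreasing = TRUE))
}

#' Aggregate sensitivity sweeps over many events
#'
#' Boxplot statistics (median, quartiles, 2.5/97.5 percentiles) of the
#' first-order indices across events, per input and lead time.
#'
#' @param sweeps list of sweep results from [leadTimeSweep()], one per
#'   event.
#' @return data.frame with one row per (input, lead time): `median`, `q1`,
#'   `q3`, `p2.5`, `p97.5`, `n_events`.
#' @export
aggregateSweeps <- function(sweeps) {
  stopIfNot(length(sweeps) >= 1, "need at least one event sweep")
  tab <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
    t <- sweeps[[i]]$table
    t$event <- i
    t
  }))
  agg <- function(d) data.frame(
    input = d$input[1L], lead_time_days = d$lead_time_days[1L],
    median = stats::median(d$S1),
    q1 = stats::quantile(d$S1, 0.25, names = FALSE),
    q3 = stats::quantile(d$S1, 0.75, names = FALSE),
    p2.5 = stats::quantile(d$S1, 0.025, names = FALSE),
    p97.5 = stats::quantile(d$S1, 0.975, names = FALSE),
    n_events = nrow(d))
  parts <- split(tab, list(tab$input, tab$lead_time_days), drop = TRUE)
  out <- do.call(rbind, lapply(parts, agg))
  rownames(out) <- NULL
  out[order(-out$lead_time_days, out$input), ]
}
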