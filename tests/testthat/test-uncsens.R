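test_that("Saltelli design has the prescribed size and determinism", {
  d <- buildDesign(n_members = 51, bundle_size = 4, base_n = 2048, seed = 1)
  expect_equal(d$total_runs, 10240)   # base_n * (D + 2), above 8000
  d8 <- buildDesign(base_n = 8, seed = 1)
  expect_equal(d8$total_runs, 40)
  expect_error(buildDesign(base_n = 1000), "power of two")
  expect_error(buildDesign(base_n = 8, scale_range = c(1.2, 0.8)),
               "scale_range")
  # determinism and unit-cube support
  d2 <- buildDesign(n_members = 51, bundle_size = 4, base_n = 2048, seed = 1)
  expect_identical(d$A, d2$A)
  expect_identical(d$B, d2$B)
  expect_true(all(d$A >= 0 & d$A < 1) && all(d$B >= 0 & d$B < 1))
  d3 <- buildDesign(base_n = 2048, seed = 2)
  expect_false(identical(d$A, d3$A))
  # AB_i differs from A only in column i
  for (i in 1:3) {
    M <- d$AB[, , i]
    expect_identical(M[, i], d$B[, i])
    expect_identical(M[, -i], d$A[, -i])
  }
})

test_that("unit-cube points map to members, scales and functions", {
  space <- list(n_members = 51, bundle_size = 4, scale_range = c(0.8, 1.2))
  m <- mapUnits(rbind(c(0, 0.5, 0), c(0.999, 0, 0.999), c(0.5, 1 - 1e-9, 0.3)),
                space)
  expect_equal(m$member, c(0, 50, 25))
  expect_equal(m$scale, c(1.0, 0.8, 1.2), tolerance = 1e-6)
  expect_equal(m$fun, c(0, 3, 1))
  # scale endpoints span exactly [0.8, 1.2]
  expect_equal(mapUnits(c(0, 0, 0), space)$scale, 0.8)
  expect_equal(mapUnits(c(0, 1, 0), space)$scale, 1.2)
})

test_that("Sobol estimator matches analytic Ishigami indices", {
  base_n <- 4096
  d <- buildDesign(base_n = base_n, seed = 5)
  ishigami <- function(U) {
    X <- -pi + 2 * pi * U
    sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  }
  fA <- ishigami(d$A); fB <- ishigami(d$B)
  fAB <- vapply(1:3, function(i) ishigami(d$AB[, , i]), numeric(base_n))
  s <- sobolFirstOrder(fA, fB, fAB, inputs = c("x1", "x2", "x3"),
                       n_boot = 200, seed = 1)
  expect_equal(s$S1, c(0.3139, 0.4424, 0), tolerance = 0.03,
               ignore_attr = TRUE)
  expect_true(all(s$ci_low <= s$S1 & s$S1 <= s$ci_high))
  # plain Monte Carlo cross-check of the same estimator (larger n: plain MC
  # converges slower than the low-discrepancy design)
  n_mc <- 32768
  mc <- withr::with_seed(2, matrix(runif(n_mc * 6), ncol = 6))
  A <- mc[, 1:3]; B <- mc[, 4:6]
  fABmc <- vapply(1:3, function(i) { M <- A; M[, i] <- B[, i]; ishigami(M) },
                  numeric(n_mc))
  smc <- sobolFirstOrder(ishigami(A), ishigami(B), fABmc, n_boot = 0)
  expect_equal(smc$S1, c(0.3139, 0.4424, 0), tolerance = 0.06,
               ignore_attr = TRUE)
})

test_that("estimator handles single-active, additive and constant outputs", {
  d <- buildDesign(base_n = 1024, seed = 3)
  pass2 <- function(U) U[, 2]
  s <- sobolFirstOrder(pass2(d$A), pass2(d$B),
                       vapply(1:3, function(i) pass2(d$AB[, , i]),
                              numeric(1024)), n_boot = 100)
  expect_equal(s$S1, c(0, 1, 0), tolerance = 0.05, ignore_attr = TRUE)
  # constant output: all indices defined as zero
  s0 <- sobolFirstOrder(rep(3, 1024), rep(3, 1024),
                        matrix(3, 1024, 3), n_boot = 10)
  expect_equal(s0$S1, c(0, 0, 0))
  # additive model: indices sum to one within estimator noise
  add <- function(U) U[, 1] + U[, 2] + U[, 3]
  sa <- sobolFirstOrder(add(d$A), add(d$B),
                        vapply(1:3, function(i) add(d$AB[, , i]),
                               numeric(1024)), n_boot = 0)
  expect_equal(sum(sa$S1), 1, tolerance = 0.05)
  expect_error(sobolFirstOrder(1:10, 1:9, matrix(0, 10, 3)), "match")
})

test_that("estimator noise shrinks as the design grows", {
  add <- function(U) U[, 1] + U[, 2] + U[, 3]
  err <- vapply(c(256, 1024, 4096), function(n) {
    d <- buildDesign(base_n = n, seed = 9)
    s <- sobolFirstOrder(add(d$A), add(d$B),
                         vapply(1:3, function(i) add(d$AB[, , i]),
                                numeric(n)), n_boot = 0)
    max(abs(s$S1 - 1 / 3))
  }, numeric(1))
  expect_true(all(err > -0.05 & err < 0.2))
  expect_lt(err[3], err[1] + 1e-12)
  expect_lt(err[3], 0.02)
})

test_that("cached run evaluation equals naive re-evaluation", {
  fx <- .fx()
  ens5 <- tcEnsemble(ensembleMembers(fx$ensemble)[1:5])
  bundle <- selectBundle(lapply(c(50, 60, 70), function(vh)
    impactFunction(vh, event_id = sprintf("E%d", vh))),
    impactFunction(60), q = 1)
  d <- buildDesign(n_members = 5, bundle_size = 3, base_n = 4, seed = 2)
  fast <- runSamples(d, ens5, fx$exposure, bundle)
  slow <- runSamples(d, ens5, fx$exposure, bundle, hazards = fast$hazards,
                     naive = TRUE)
  expect_equal(fast$totals, slow$totals, tolerance = 1e-9)
  expect_equal(length(fast$totals), d$total_runs)
})

test_that("inert inputs earn near-zero indices in the full model", {
  fx <- .fx()
  # zero ensemble spread + single function: only the scale input is active
  p <- trackPoints(fx$parent)
  same <- tcEnsemble(lapply(0:10, function(i)
    tcTrack(p$time, p$lat, p$lon, p$p_cen, p$p_env, member_id = i)))
  b1 <- new("FunctionBundle", region_id = "R", best = impactFunction(60),
            members = list(impactFunction(60)))
  expect_warning(
    ua <- uncertaintyAnalysis(same, fx$exposure, b1, base_n = 256,
                              n_boot = 50, seed = 4),
    "inert")
  expect_equal(ua$indices$S1[ua$indices$input == "scale"], 1,
               tolerance = 0.05)
  expect_equal(ua$indices$S1[ua$indices$input != "scale"], c(0, 0),
               tolerance = 0.05, ignore_attr = TRUE)
  # all members missing land: all totals zero
  far <- makeHitMissEnsemble(fx$parent, n = 5, miss_fraction = 1,
                             island_radius_km = fx$cfg$island_radius_km)
  d <- buildDesign(n_members = 5, bundle_size = 1, base_n = 4, seed = 1)
  z <- runSamples(d, far, fx$exposure, b1)
  expect_true(all(z$totals == 0))
})

test_that("dominant-input map flags scale-driven and inert cells", {
  fx <- .fx()
  p <- trackPoints(fx$parent)
  same <- tcEnsemble(lapply(0:3, function(i)
    tcTrack(p$time, p$lat, p$lon, p$p_cen, p$p_env, member_id = i)))
  b1 <- new("FunctionBundle", region_id = "R", best = impactFunction(60),
            members = list(impactFunction(60)))
  d <- buildDesign(n_members = 4, bundle_size = 1, base_n = 64, seed = 6)
  dom <- perCellDominant(d, same, fx$exposure, b1)
  v <- gridValues(dom)
  pop <- gridValues(fx$exposure)
  hz <- gridValues(computeWindfield(parentTrack(same), fx$exposure))
  active <- pop > 0 & hz > 25.7
  # populated, wind-affected cells scale linearly with u2 -> dominant scale
  expect_true(all(v[active] == 2))
  # unaffected cells have no dominant input
  expect_true(all(v[!active] == 0))
})

test_that("lead-time sweep orders results by lead time", {
  fx <- .fx()
  # member spread is the only substantially active input: one function,
  # near-degenerate exposure scaling
  b1 <- new("FunctionBundle", region_id = "R", best = impactFunction(60),
            members = list(impactFunction(60)))
  cfg <- fx$cfg
  parent <- fx$parent
  # two init times, 12 h apart: drop the first two fixes of the parent
  p <- trackPoints(parent)
  later <- tcTrack(p$time[-(1:2)], p$lat[-(1:2)], p$lon[-(1:2)],
                   p$p_cen[-(1:2)], p$p_env[-(1:2)])
  # spread shrinking toward landfall: no position noise at the later init
  cfg_late <- cfg; cfg_late$sigma_xy_km <- 0; cfg_late$sigma_p_hpa <- 0
  ens_early <- makeEnsemble(parent, cfg, n = 7, seed = 2)
  ens_late <- makeEnsemble(later, cfg_late, n = 7, seed = 2)
  sw <- suppressWarnings(
    leadTimeSweep(list(ens_early, ens_late), fx$exposure, b1,
                  fx$land_mask, base_n = 64, n_boot = 20, seed = 3,
                  scale_range = c(0.999, 1.001)))
  expect_equal(sort(unique(sw$table$lead_time_days), decreasing = TRUE),
               sw$lead_time_days)
  expect_gt(sw$lead_time_days[1], sw$lead_time_days[2])
  expect_equal(nrow(sw$table), 6)   # 3 inputs x 2 lead times
  # shrinking-spread construction: distribution narrows toward landfall
  sds <- vapply(sw$runs, function(r) stats::sd(r$totals), numeric(1))
  expect_lte(sds[2], sds[1])
  # with zero ensemble spread the member input is inert
  late_tab <- sw$table[sw$table$lead_time_days == sw$lead_time_days[2], ]
  expect_equal(late_tab$S1[late_tab$input == "member"], 0, tolerance = 0.05)
  # degenerate single init time works
  sw1 <- suppressWarnings(
    leadTimeSweep(list(ens_early), fx$exposure, b1, fx$land_mask,
                  base_n = 64, n_boot = 0, seed = 3))
  expect_equal(nrow(sw1$table), 3)
})

test_that("multi-event aggregation produces coherent boxplot statistics", {
  mkTab <- function(s_member) {
    list(table = data.frame(
      input = c("member", "scale", "function"),
      S1 = c(s_member, 0.2, 0.5), ci_low = NA, ci_high = NA,
      lead_time_days = 2, mean = 1000, sd = 100))
  }
  # single event: box collapses onto the point estimate
  a1 <- aggregateSweeps(list(mkTab(0.4)))
  expect_equal(a1$median, a1$q1)
  expect_equal(a1$median, a1$p97.5)
  # identical events: zero IQR
  a2 <- aggregateSweeps(list(mkTab(0.4), mkTab(0.4), mkTab(0.4)))
  expect_equal(a2$q3 - a2$q1, rep(0, 3))
  # median between quartiles
  a3 <- aggregateSweeps(lapply(c(0.1, 0.4, 0.7), mkTab))
  expect_true(all(a3$median >= a3$q1 & a3$median <= a3$q3))
  expect_equal(a3$n_events, rep(3, 3))
})
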