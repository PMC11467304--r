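test_that("sigmoid impact function hits its anchor points", {
  f <- impactFunction(v_half = 60, v_thresh = 25.7, scale = 0.8)
  expect_identical(displacedFraction(f, 25.7), 0)
  expect_identical(displacedFraction(f, 10), 0)
  expect_equal(displacedFraction(f, 60), 0.4)     # scale / 2 at v_half
  expect_equal(displacedFraction(f, 1e6), 0.8, tolerance = 1e-9)
  V <- seq(0, 120, by = 0.5)
  expect_true(all(diff(displacedFraction(f, V)) >= 0))
  # non-increasing in v_half at fixed V > v_thresh
  fr <- vapply(seq(30, 140, by = 5),
               function(vh) displacedFraction(impactFunction(vh), 50),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(impactFunction(20, v_thresh = 25.7), "exceed")
  expect_error(impactFunction(60, scale = 0), "scale")
})

test_that("RMSF closed forms and invariances hold", {
  o <- c(100, 2000, 50000)
  expect_equal(rmsf(o, o), 1)
  expect_equal(rmsf(2 * o, o), 2)
  expect_equal(rmsf(o / 2, o), 2)
  # ratios {2, 1/2}: RMS of {ln 2, -ln 2} is ln 2
  expect_equal(rmsf(c(200, 50), c(100, 100)), 2)
  # scale invariance
  m <- c(123, 4567, 89)
  expect_equal(rmsf(7 * m, 7 * o), rmsf(m, o))
  expect_error(rmsf(numeric(0), numeric(0)), "empty")
  expect_error(rmsf(1:3, 1:2), "mismatch")
})

# deterministic grid-scan oracle for the best v_half
gridScanVhalf <- function(objective, bounds = c(25.8, 150), step = 0.05) {
  vh <- seq(bounds[1], bounds[2], by = step)
  vh[which.min(vapply(vh, objective, numeric(1)))]
}

test_that("per-event calibration inverts the forward model", {
  cat0 <- makeEventCatalog(3, impactFunction(60), sigma = 0, cfg = fixCfg(),
                           seed = 11)
  ev <- cat0$events[[1]]
  f <- calibrateEvent(ev, cat0$exposure)
  expect_equal(vHalf(f), 60, tolerance = 0.02)
  # grid-scan oracle on the squared error agrees
  obj <- function(vh) (sum(gridValues(cat0$exposure) *
    displacedFraction(impactFunction(vh), gridValues(ev$hazard))) -
    ev$reported)^2
  expect_equal(vHalf(f), gridScanVhalf(obj), tolerance = 0.06)
  # larger reported displacement -> smaller fitted v_half
  ev_hi <- eventRecord(ev$event_id, ev$region_id, ev$reported * 3, ev$hazard)
  expect_lt(vHalf(calibrateEvent(ev_hi, cat0$exposure)), vHalf(f))
  # unattainably large reported value clamps at the lower bound
  ev_max <- eventRecord(ev$event_id, ev$region_id, 1e9, ev$hazard)
  expect_equal(vHalf(calibrateEvent(ev_max, cat0$exposure)), 25.8)
  # zero-impact event yields the unusable sentinel
  ev0 <- eventRecord(ev$event_id, ev$region_id, 0, ev$hazard)
  expect_false(isUsable(calibrateEvent(ev0, cat0$exposure)))
})

test_that("regional RMSF calibration recovers a noise-free truth", {
  cat0 <- makeEventCatalog(6, impactFunction(60), sigma = 0, cfg = fixCfg(),
                           seed = 21)
  best <- calibrateRegion(cat0$events, cat0$exposure)
  expect_equal(vHalf(best), 60, tolerance = 1 / 60)
  expect_equal(attr(best, "rmsf"), 1, tolerance = 0.01)
  # single event: regional fit reduces to the per-event fit
  one <- calibrateRegion(cat0$events[1], cat0$exposure)
  expect_equal(vHalf(one), vHalf(calibrateEvent(cat0$events[[1]],
                                                cat0$exposure)),
               tolerance = 0.05)
  # doubling all reported impacts strictly decreases the fitted v_half
  dbl <- lapply(cat0$events, function(e)
    eventRecord(e$event_id, e$region_id, 2 * e$reported, e$hazard))
  expect_lt(vHalf(calibrateRegion(dbl, cat0$exposure)), vHalf(best))
  z <- lapply(cat0$events, function(e)
    eventRecord(e$event_id, e$region_id, 0, e$hazard))
  expect_error(calibrateRegion(z, cat0$exposure), "zero")
})

test_that("noisy calibration recovers v_half within ten percent", {
  cat1 <- makeEventCatalog(30, impactFunction(60), sigma = 0.2,
                           cfg = fixCfg(), seed = 33)
  best <- calibrateRegion(cat1$events, cat1$exposure)
  expect_lt(abs(vHalf(best) - 60) / 60, 0.10)
})

test_that("bundle selection keeps the central 80% by rank", {
  mk <- function(vh, id) impactFunction(vh, event_id = id)
  funcs <- Map(mk, seq(40, 85, by = 5), sprintf("E%02d", 1:10))
  best <- impactFunction(60, region_id = "R1")
  b <- selectBundle(funcs, best, q = 0.80)
  vh <- sort(vapply(bundleMembers(b), vHalf, numeric(1)))
  expect_equal(vh, seq(45, 80, by = 5))  # min and max dropped, 8 kept
  expect_equal(length(bundleMembers(selectBundle(funcs, best, q = 1))), 10)
  same <- Map(mk, rep(60, 5), sprintf("E%02d", 1:5))
  expect_equal(length(bundleMembers(selectBundle(same, best))), 5)
  expect_error(selectBundle(funcs[1:2], best), ">= 3")
  # unusable sentinels are excluded before ranking
  funcs2 <- c(funcs, list(impactFunction(150, event_id = "E99",
                                         usable = FALSE)))
  b2 <- selectBundle(funcs2, best, q = 0.80)
  expect_equal(length(bundleMembers(b2)), 8)
})

test_that("impact functions and bundles survive a JSON round trip", {
  best <- impactFunction(61.25, region_id = "R1")
  funcs <- Map(function(vh, id) impactFunction(vh, event_id = id,
                                               region_id = "R1"),
               c(50, 60, 70), c("A", "B", "C"))
  b <- selectBundle(funcs, best, q = 1)
  path <- tempfile(fileext = ".json")
  writeImpactFunctions(b, path)
  back <- readImpactFunctions(path)
  expect_s4_class(back, "FunctionBundle")
  expect_equal(vHalf(bundleBest(back)), 61.25)
  expect_equal(vapply(bundleMembers(back), vHalf, numeric(1)), c(50, 60, 70))
})
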