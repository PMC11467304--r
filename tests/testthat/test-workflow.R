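# end-to-end orchestration on files written to a temp dir

writeFixtures <- function(dir, n_members = 11, n_cells = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fixCfg(n_cells = n_cells)
  parent <- makeParentTrack(cfg)
  ens <- makeEnsemble(parent, cfg, n = n_members)
  pop <- makePopulation(cfg)
  writeTracks(ens, file.path(dir, "tracks.csv"))
  writePopulation(pop$exposure, file.path(dir, "population.asc"))
  cycloneImpact:::writeGridAscii(pop$land_mask,
                                 file.path(dir, "land_mask.asc"))
  writeImpactFunctions(impactFunction(60, region_id = "R1"),
                       file.path(dir, "function.json"))
  bundle <- selectBundle(lapply(c(50, 60, 70), function(vh)
    impactFunction(vh, event_id = sprintf("E%d", vh), region_id = "R1")),
    impactFunction(60, region_id = "R1"), q = 1)
  writeImpactFunctions(bundle, file.path(dir, "bundle.json"))
  list(dir = dir, cfg = cfg, parent = parent)
}

test_that("forecast run writes member totals, mean map and summary", {
  fxd <- writeFixtures(tempfile("wf"))
  out <- file.path(fxd$dir, "out")
  cfg <- list(tracks = file.path(fxd$dir, "tracks.csv"),
              exposure = file.path(fxd$dir, "population.asc"),
              impact_function = file.path(fxd$dir, "function.json"),
              out_dir = out)
  res <- suppressMessages(runForecast(cfg))
  tab <- read.csv(file.path(out, "member_totals.csv"))
  expect_equal(nrow(tab), 11)
  expect_equal(res$summary$mean, mean(tab$total), tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "mean_impact_map.asc")))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$n_members, 11)
  # rerun is byte-identical
  tab1 <- readLines(file.path(out, "member_totals.csv"))
  suppressMessages(runForecast(cfg))
  expect_identical(readLines(file.path(out, "member_totals.csv")), tab1)
  # missing input fails fast with the offending path
  bad <- cfg; bad$tracks <- file.path(fxd$dir, "nope.csv")
  expect_error(suppressMessages(runForecast(bad)), "missing input.*nope")
})

test_that("uncertainty run writes samples and a 3-row index table", {
  fxd <- writeFixtures(tempfile("wf"))
  out <- file.path(fxd$dir, "out")
  cfg <- list(tracks = file.path(fxd$dir, "tracks.csv"),
              exposure = file.path(fxd$dir, "population.asc"),
              bundle = file.path(fxd$dir, "bundle.json"),
              out_dir = out, base_n = 64, n_boot = 20, seed = 11,
              dominant_map = TRUE)
  res <- suppressMessages(runUncsens(cfg))
  samples <- read.csv(file.path(out, "samples.csv"))
  expect_equal(nrow(samples), 64 * 5)
  idx <- read.csv(file.path(out, "sensitivity.csv"))
  expect_equal(nrow(idx), 3)
  expect_setequal(idx$input, c("member", "scale", "function"))
  expect_true(file.exists(file.path(out, "dominant_map.asc")))
  expect_true(file.exists(file.path(out, "dominant_map_legend.json")))
})

test_that("sweep run indexes outputs by lead time", {
  fxd <- writeFixtures(tempfile("wf"))
  # second init time: 12 h later, first two fixes dropped
  p <- trackPoints(fxd$parent)
  later <- tcTrack(p$time[-(1:2)], p$lat[-(1:2)], p$lon[-(1:2)],
                   p$p_cen[-(1:2)], p$p_env[-(1:2)])
  ens2 <- makeEnsemble(later, fxd$cfg, n = 11)
  writeTracks(ens2, file.path(fxd$dir, "tracks_late.csv"))
  out <- file.path(fxd$dir, "out_sweep")
  cfg <- list(tracks = c(file.path(fxd$dir, "tracks.csv"),
                         file.path(fxd$dir, "tracks_late.csv")),
              exposure = file.path(fxd$dir, "population.asc"),
              bundle = file.path(fxd$dir, "bundle.json"),
              land_mask = file.path(fxd$dir, "land_mask.asc"),
              out_dir = out, base_n = 32, n_boot = 10)
  res <- suppressMessages(runSweep(cfg))
  tab <- read.csv(file.path(out, "sweep_indices.csv"))
  expect_equal(nrow(tab), 6)
  expect_true("lead_time_days" %in% names(tab))
  expect_equal(length(unique(tab$lead_time_days)), 2)
  # rows come out ordered by decreasing lead time
  expect_true(!is.unsorted(rev(tab$lead_time_days)))
  # unordered init times are sorted with a warning
  cfg2 <- cfg
  cfg2$tracks <- rev(cfg$tracks)
  cfg2$out_dir <- file.path(fxd$dir, "out_sweep2")
  expect_warning(suppressMessages(runSweep(cfg2)), "sorting")
})

test_that("yaml config files drive the same runs", {
  fxd <- writeFixtures(tempfile("wf"))
  out <- file.path(fxd$dir, "out_yaml")
  ypath <- file.path(fxd$dir, "cfg.yaml")
  writeLines(c(paste0("tracks: ", file.path(fxd$dir, "tracks.csv")),
               paste0("exposure: ", file.path(fxd$dir, "population.asc")),
               paste0("impact_function: ", file.path(fxd$dir, "function.json")),
               paste0("out_dir: ", out)), ypath)
  res <- suppressMessages(runForecast(ypath))
  expect_equal(res$summary$n_members, 11)
})
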