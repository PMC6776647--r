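## Cascade orchestration tests use plug-in models where the behaviour must
## be forced, and the cached trained models where realism matters.

neverWhale <- function(patch) c(whale = 0, ship = 0, water_rock = 1)
noDetections <- function(patch) {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), class = character(0), score = numeric(0))
}

test_that("a classifier that never fires passes no cell and counts nothing", {
  site <- testSite()
  det <- testDetector()
  rep <- runCascade(site$scenes[1:2], neverWhale, det, cascadeConfig())
  expect_equal(rep@cellsPassed, 0L)
  expect_equal(rep@detectorCalls, 0L)
  expect_equal(totalWhaleCount(rep), 0L)
  expect_true(all(!reportCells(rep)$passed))
  expect_equal(nrow(reportDetections(rep)), 0L)
})

test_that("cells that fail stage-1 carry no detections and zero counts", {
  site <- testSite()
  rep <- runCascade(site$scenes, testClassifier(), testDetector(),
                    cascadeConfig())
  cells <- reportCells(rep)
  expect_true(all(cells$whale_count[!cells$passed] == 0L))
  expect_lte(rep@detectorCalls, rep@totalCells)
  expect_equal(rep@detectorCalls, rep@cellsPassed)
  expect_equal(totalWhaleCount(rep), nrow(reportDetections(rep)))
  expect_equal(totalWhaleCount(rep), sum(cells$whale_count))
  ## stage-1 probabilities are simplex rows
  expect_true(all(abs(cells$p_whale + cells$p_ship +
                      cells$p_water_rock - 1) < 1e-6))
})

test_that("with the threshold rule at zero the cascade equals the baseline", {
  site <- testSite()
  clf <- testClassifier(); det <- testDetector()
  cfg0 <- cascadeConfig(presence_rule = "threshold", presence_threshold = 0)
  cas <- runCascade(site$scenes, clf, det, cfg0)
  bas <- runBaseline(site$scenes, det, cfg0)
  expect_equal(cas@cellsPassed, cas@totalCells)
  expect_equal(cas@detectorCalls, bas@detectorCalls)
  expect_equal(totalWhaleCount(cas), totalWhaleCount(bas))
  expect_equal(reportDetections(cas)[, c("x_min", "y_min", "x_max", "y_max",
                                         "score")],
               reportDetections(bas)[, c("x_min", "y_min", "x_max", "y_max",
                                         "score")])
  expect_equal(bas@mode, "baseline")
  ## baseline analyses every cell by definition
  expect_equal(bas@detectorCalls, bas@totalCells)
})

test_that("lowering the presence threshold is monotone in cells passed", {
  site <- testSite()
  clf <- testClassifier(); det <- testDetector()
  taus <- c(0.9, 0.5, 0.2, 0)
  passed <- integer(0); counts <- integer(0)
  for (tau in taus) {
    r <- runCascade(site$scenes[1:3], clf, det,
                    cascadeConfig(presence_rule = "threshold",
                                  presence_threshold = tau))
    passed <- c(passed, r@cellsPassed)
    counts <- c(counts, totalWhaleCount(r))
  }
  expect_true(all(diff(passed) >= 0))
  expect_true(all(diff(counts) >= 0))
})

test_that("detections are merged across cell borders without double counts", {
  ## a detector that fires the same scene-spanning whale in every cell it
  ## sees would double count without cross-cell NMS; build a whale sitting
  ## on a cell border and check it is counted once
  g <- generateScene(sceneSpec(width_m = 142, height_m = 71, n_whales = 0,
                               seed = 5))
  img <- sceneImage(g$scene)
  ## paint a bright elongated blob straddling x = 71
  img[30:38, 62:82, ] <- img[30:38, 62:82, ] + 0.25
  sc <- Scene(whalescan:::clampRange(img), 1, siteId = "border")
  det <- testDetector()
  rep <- runBaseline(sc, det, cascadeConfig())
  expect_equal(totalWhaleCount(rep), nrow(reportDetections(rep)))
  ## the blob spans two cells but is counted at most once after merging
  d <- reportDetections(rep)
  overlapping <- d[d$x_min < 82 & d$x_max > 62 & d$y_min < 38 & d$y_max > 30, ]
  expect_lte(nrow(overlapping), 1L)
})

test_that("empty scene lists and empty reports aggregate cleanly", {
  det <- testDetector()
  rep <- runBaseline(list(), det, cascadeConfig())
  expect_equal(rep@totalCells, 0L)
  expect_equal(totalWhaleCount(rep), 0L)
  agg <- aggregateSites(list(rep))
  expect_equal(agg$totals$whale_count, 0)
  expect_error(runCascade(list(), NULL, det), "classifier")
})

test_that("multi-site aggregation sums per-site rows and checks config", {
  site <- testSite()
  det <- testDetector()
  cfg <- cascadeConfig()
  r1 <- runBaseline(site$scenes[[1]], det, cfg)
  r2 <- runBaseline(site$scenes[[2]], det, cfg)
  agg <- aggregateSites(list(r1, r2))
  expect_equal(nrow(agg$per_site), 2L)
  expect_equal(agg$totals$total_cells, r1@totalCells + r2@totalCells)
  expect_equal(agg$totals$whale_count,
               totalWhaleCount(r1) + totalWhaleCount(r2))
  ## single report aggregates to itself
  one <- aggregateSites(list(r1))
  expect_equal(one$totals$total_cells, r1@totalCells)
  ## mixed configs refuse unless forced
  r3 <- runBaseline(site$scenes[[3]], det, cascadeConfig(nms_iou = 0.3))
  expect_error(aggregateSites(list(r1, r3)), "config hash")
  forced <- aggregateSites(list(r1, r3), force = TRUE)
  expect_equal(nrow(forced$per_site), 2L)
})

test_that("published per-site tallies aggregate to the survey totals", {
  tal <- hotspotCellTallies()
  expect_equal(nrow(tal), 10L)
  agg <- aggregateSites(tal)
  tot <- agg[agg$site == "Total", ]
  expect_equal(tot$whale_cells_photo, 68)
  expect_equal(tot$whale_cells_model, 56)
  expect_equal(tot$total_cells, 13348)
})

test_that("cascade configs validate and reports expose provenance", {
  expect_error(cascadeConfig(presence_threshold = 2), "0, 1")
  expect_error(cascadeConfig(cell_size_m = -1), "positive")
  site <- testSite()
  rep <- runBaseline(site$scenes[[1]], testDetector(), cascadeConfig(seed = 9))
  expect_equal(rep@provenance$seed, 9L)
  expect_true(nzchar(rep@provenance$config_hash))
  expect_true(nzchar(rep@provenance$detector_id))
})
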