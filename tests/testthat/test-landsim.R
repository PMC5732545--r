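test_that("configs validate their invariants", {
  expect_error(landscapeConfig(rows = 0, cols = 10), "rows")
  expect_error(landscapeConfig(farmlandFraction = 1.2), "farmlandFraction")
  expect_error(landscapeConfig(ndviMonths = 0), "ndviMonths")
  expect_error(responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = 2, high = 1,
                            penalty = 0)), "low < high")
  expect_error(responseConfig(dispersion = 0.5), "dispersion")
})

test_that("landscape generation is deterministic under a fixed seed", {
  cfg <- landscapeConfig(rows = 50, cols = 50, seed = 5)
  a <- generateLandscape(cfg)
  b <- generateLandscape(cfg)
  expect_identical(lapply(a@featureMasks, gridValues),
                   lapply(b@featureMasks, gridValues))
  expect_identical(gridValues(a@farmland), gridValues(b@farmland))
  expect_identical(lapply(a@ndvi, gridValues), lapply(b@ndvi, gridValues))
})

test_that("every requested feature class is non-empty and masks are binary", {
  lsc <- smallLandscape(3)
  for (cl in featureClasses()) {
    v <- gridValues(lsc@featureMasks[[cl]])
    expect_true(all(v %in% c(0, 1)))
    if (lsc@config@featureCounts[[cl]] > 0) expect_gt(sum(v), 0)
  }
  for (g in lsc@ndvi) {
    v <- gridValues(g)
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("farmland fraction is honored at the boundaries and in expectation", {
  allFarm <- generateLandscape(
    landscapeConfig(rows = 20, cols = 20, farmlandFraction = 1, seed = 1))
  expect_true(all(gridValues(allFarm@farmland) == 1))
  noFarm <- generateLandscape(
    landscapeConfig(rows = 20, cols = 20, farmlandFraction = 0, seed = 1))
  expect_true(all(gridValues(noFarm@farmland) == 0))
  fracs <- vapply(1:10, function(s) {
    lsc <- generateLandscape(landscapeConfig(rows = 200, cols = 200,
                                             farmlandFraction = 0.5,
                                             seed = s))
    mean(gridValues(lsc@farmland))
  }, 0)
  expect_true(all(abs(fracs - 0.5) <= 0.05))
})

test_that("NDVI fields are spatially autocorrelated", {
  lsc <- smallLandscape(8)
  v <- gridValues(lsc@ndvi[[1]])
  lagCor <- cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  expect_gt(lagCor, 0.5)
})

test_that("true surfaces evaluate the plateau product formula", {
  lsc <- smallLandscape(2)
  st <- buildStack(lsc)
  # single kernel, value inside the plateau -> p equals the maximum (1)
  single <- responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = -1, high = 1,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1),
    lambdaMax = 5, dispersion = 1, nSites = 10L)
  surf <- trueSurfaces(lsc, single, st)
  expect_true(all(gridValues(surf$p) == 1))
  expect_true(all(gridValues(surf$lambda) == 5))
  # all predictors outside their ranges with penalty 0 -> p identically 0
  none <- responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = 2, high = 3,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1),
    lambdaMax = 5, dispersion = 1, nSites = 10L)
  expect_true(all(gridValues(trueSurfaces(lsc, none, st)$p) == 0))
  # random pixels match an independent re-evaluation of the product
  resp <- stairResponse()
  surf2 <- trueSurfaces(lsc, resp, st)
  raw <- matrix(1, 60, 60)
  for (i in seq_len(nrow(resp@occurrence))) {
    v <- gridValues(stackLayers(st)[[resp@occurrence$predictor[i]]])
    raw <- raw * ifelse(v >= resp@occurrence$low[i] &
                          v <= resp@occurrence$high[i], 1,
                        resp@occurrence$penalty[i])
  }
  raw <- raw / max(raw)
  set.seed(1)
  idx <- sample(3600, 50)
  expect_equal(gridValues(surf2$p)[idx], raw[idx])
  expect_error(trueSurfaces(lsc, responseConfig(
    occurrence = data.frame(predictor = "no_such", low = 0, high = 1,
                            penalty = 0.1),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1))), "unknown predictor")
})

test_that("simulated counts have the configured mean under Poisson noise", {
  lsc <- smallLandscape(4)
  flat <- responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = -1, high = 1,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1),
    lambdaMax = 5, dispersion = 1, nSites = 1000L)
  obs <- simulateObservations(lsc, flat, seed = 1)
  counts <- observations(obs)$count
  expect_length(counts, 1000L)
  # zero-truncated Poisson(5) has mean 5 / (1 - exp(-5)) ~ 5.034
  expect_lt(abs(mean(counts) - 5), 0.5)
  expect_true(all(counts >= 1))
})

test_that("overdispersed counts have variance exceeding the mean", {
  lsc <- generateLandscape(landscapeConfig(rows = 110, cols = 110, seed = 6))
  od <- responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = -1, high = 1,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1),
    lambdaMax = 8, dispersion = 6, nSites = 10000L)
  counts <- observations(simulateObservations(lsc, od, seed = 2))$count
  expect_length(counts, 10000L)
  expect_gt(var(counts), mean(counts))
})

test_that("presence points only fall where p is positive", {
  lsc <- smallLandscape(5)
  nearRiver <- responseConfig(
    occurrence = data.frame(predictor = "dist_rivers", low = 0, high = 300,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1),
    lambdaMax = 5, dispersion = 1, nSites = 40L)
  obs <- simulateObservations(lsc, nearRiver, seed = 3)
  d <- extractAtPoints(buildStack(lsc), obs)
  expect_true(all(d$dist_rivers <= 300))
})

test_that("observation simulation is deterministic and errors on zero p", {
  lsc <- smallLandscape(6)
  resp <- stairResponse(nSites = 50L)
  a <- simulateObservations(lsc, resp, seed = 9)
  b <- simulateObservations(lsc, resp, seed = 9)
  expect_identical(observations(a), observations(b))
  zero <- responseConfig(
    occurrence = data.frame(predictor = "mnndvi", low = 2, high = 3,
                            penalty = 0),
    abundance = data.frame(predictor = "mnndvi", low = -1, high = 1,
                           penalty = 1), nSites = 10L)
  expect_error(simulateObservations(lsc, zero, seed = 1), "identically zero")
})

test_that("presence density across 20 seeds tracks the true p surface", {
  lsc <- generateLandscape(landscapeConfig(rows = 100, cols = 100, seed = 11))
  st <- buildStack(lsc)
  resp <- stairResponse()
  tru <- trueSurfaces(lsc, resp, st)
  cnt <- matrix(0, 100, 100)
  for (seed in 1:20) {
    pts <- observations(simulateObservations(lsc, resp, seed, stack = st))
    tc <- pointToCell(tru$p, pts$x, pts$y)
    idx <- cbind(tc$row, tc$col)
    for (i in seq_len(nrow(idx)))
      cnt[idx[i, 1], idx[i, 2]] <- cnt[idx[i, 1], idx[i, 2]] + 1
  }
  expect_gt(cor(as.vector(cnt), as.vector(gridValues(tru$p)),
                method = "spearman"), 0.5)
})

test_that("landscape, observations and config round-trip through disk", {
  lsc <- smallLandscape(7, rows = 20L, cols = 20L)
  dir <- withr::local_tempdir()
  paths <- writeLandscape(lsc, dir)
  expect_true(all(file.exists(paths)))
  back <- readAsciiGrid(file.path(dir, "mask_pools.asc"))
  expect_identical(gridValues(back), gridValues(lsc@featureMasks$pools))

  resp <- stairResponse(nSites = 30L)
  obs <- simulateObservations(lsc, resp, seed = 1)
  f <- file.path(dir, "obs.csv")
  writeObservations(obs, f)
  obs2 <- readObservations(f, provenance = "synthetic")
  expect_equal(observations(obs2), observations(obs))

  yf <- file.path(dir, "config.yaml")
  writeSimConfig(lsc@config, resp, yf)
  back2 <- readSimConfig(yf)
  expect_equal(back2$landscape, lsc@config)
  expect_equal(back2$response, resp)
})
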