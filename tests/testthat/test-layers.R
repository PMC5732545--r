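test_that("distance layer reproduces exact Euclidean geometry", {
  m <- matrix(0, 5, 6)
  m[1, 1] <- 1
  d <- distanceLayer(grid(m, pixelSize = 30))
  # 3 rows down, 4 cols right: the 3-4-5 triangle at 30 m pixels
  expect_equal(gridValues(d)[4, 5], 150)
  expect_equal(gridValues(d)[1, 1], 0)
  allOnes <- distanceLayer(grid(matrix(1, 4, 4), pixelSize = 30))
  expect_true(all(gridValues(allOnes) == 0))
  expect_error(distanceLayer(grid(matrix(0, 3, 3))), "empty")
})

test_that("distance layer matches the brute-force oracle on random masks", {
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(rbinom(400, 1, 0.07), 20, 20)
    if (sum(m) == 0) m[sample(400, 1)] <- 1
    s <- sample(c(10, 30, 50), 1)
    d <- gridValues(distanceLayer(grid(m, pixelSize = s)))
    expect_lt(max(abs(d - bruteDistance(m, s))), 1e-6)
  }
})

test_that("distance transform commutes with transposition", {
  set.seed(11)
  m <- matrix(rbinom(150, 1, 0.1), 10, 15)
  m[2, 3] <- 1
  d <- gridValues(distanceLayer(grid(m, pixelSize = 30)))
  dt <- gridValues(distanceLayer(grid(t(m), pixelSize = 30)))
  expect_equal(dt, t(d))
})

test_that("farmland patch area follows 4-connectivity and pixel geometry", {
  m <- matrix(0, 7, 7)
  m[2:4, 2:4] <- 1
  a <- gridValues(farmlandPatchArea(grid(m, pixelSize = 30)))
  expect_true(all(a[m == 1] == 9 * 900 / 1e6))   # 0.0081 km2
  expect_true(all(a[m == 0] == 0))
  # blocks touching only diagonally stay distinct patches
  z <- matrix(0, 7, 6)
  z[2:3, 2:3] <- 1   # 4-pixel block
  z[4:6, 4:5] <- 1   # 6-pixel block, touching the first only diagonally
  az <- gridValues(farmlandPatchArea(grid(z, pixelSize = 30)))
  expect_equal(sort(unique(az[z == 1])), c(4, 6) * 900 / 1e6)
  expect_true(all(az[2:3, 2:3] == 4 * 900 / 1e6))
  expect_true(all(az[4:6, 4:5] == 6 * 900 / 1e6))
})

test_that("patch areas match the flood-fill oracle on random masks", {
  set.seed(12)
  for (i in 1:20) {
    m <- matrix(rbinom(225, 1, 0.45), 15, 15)
    a <- gridValues(farmlandPatchArea(grid(m, pixelSize = 30)))
    expect_equal(a, brutePatchArea(m, 30))
  }
})

test_that("patch area totals conserve the farmland pixel count", {
  set.seed(13)
  m <- matrix(rbinom(400, 1, 0.5), 20, 20)
  a <- gridValues(farmlandPatchArea(grid(m, pixelSize = 30)))
  pixArea <- 900 / 1e6
  # every farmland pixel carries a positive whole-pixel-multiple area,
  # non-farmland pixels carry zero
  expect_true(all(a[m == 1] > 0))
  expect_true(all(a[m == 0] == 0))
  sizes <- a[m == 1] / pixArea
  expect_true(all(abs(sizes - round(sizes)) < 1e-9))
  # summing each patch once (patch area / patch size per pixel) recovers
  # total farmland area
  expect_equal(sum(pixArea * (a[m == 1] > 0)), sum(m) * pixArea)
})

test_that("NDVI summaries are masked pixel-wise mean and max", {
  mk <- function(v) grid(matrix(v, 2, 2), pixelSize = 30)
  s <- ndviSummaries(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_true(all(gridValues(s$mean) == 0.2))
  expect_true(all(gridValues(s$max) == 0.3))
  one <- ndviSummaries(list(mk(0.42)))
  expect_equal(gridValues(one$mean), gridValues(one$max))
  # nodata in one month: summaries use the remaining months
  a <- mk(0.1); b <- mk(0.5)
  va <- gridValues(a); va[1, 1] <- NA
  a <- gridLike(a, va)
  s2 <- ndviSummaries(list(a, b))
  expect_equal(gridValues(s2$mean)[1, 1], 0.5)
  expect_equal(gridValues(s2$max)[1, 1], 0.5)
  expect_equal(gridValues(s2$mean)[2, 2], 0.3)
  # all months nodata -> nodata
  vb <- gridValues(b); vb[1, 1] <- NA
  s3 <- ndviSummaries(list(a, gridLike(b, vb)))
  expect_true(is.na(gridValues(s3$mean)[1, 1]))
  expect_error(ndviSummaries(list(a, grid(matrix(0, 3, 3)))), "misaligned")
})

test_that("NDVI mean never exceeds max", {
  lsc <- smallLandscape(14)
  s <- ndviSummaries(lsc@ndvi)
  expect_true(all(gridValues(s$mean) <= gridValues(s$max) + 1e-12))
})

test_that("the built stack holds the eleven canonical aligned layers", {
  lsc <- smallLandscape(15, rows = 30L, cols = 30L)
  st <- buildStack(lsc)
  expect_identical(names(stackLayers(st)), predictorNames())
  expect_length(stackLayers(st), 11L)
  ref <- stackLayers(st)[[1]]
  for (g in stackLayers(st)) expect_true(gridsAligned(ref, g))
  # composition: the pool distance layer is distanceLayer of the pool mask
  expect_identical(gridValues(stackLayers(st)$dist_pools),
                   gridValues(distanceLayer(lsc@featureMasks$pools)))
  broken <- lsc
  broken@featureMasks <- lsc@featureMasks[-1]
  expect_error(buildStack(broken), "pools")
})

test_that("point extraction returns containing-pixel values", {
  lsc <- smallLandscape(16, rows = 25L, cols = 25L)
  st <- buildStack(lsc)
  ref <- stackLayers(st)[[1]]
  # a point at a pixel center gets exactly that pixel's values
  obs <- new("ObservationSet",
             points = data.frame(x = 15 + 30 * 3, y = 15 + 30 * 7,
                                 count = 2, presence = 1),
             provenance = "synthetic")
  d <- extractAtPoints(st, obs)
  for (nm in predictorNames())
    expect_equal(d[[nm]], gridValues(stackLayers(st)[[nm]])[8, 4])
  # a point one centimeter inside a pixel edge stays in that pixel
  obs2 <- new("ObservationSet",
              points = data.frame(x = 30 * 4 - 0.01, y = 30 * 8 - 0.01,
                                  count = 1, presence = 1),
              provenance = "synthetic")
  expect_equal(extractAtPoints(st, obs2)$mnndvi,
               gridValues(stackLayers(st)$mnndvi)[8, 4])
  expect_error(extractAtPoints(st, new("ObservationSet",
    points = data.frame(x = -5, y = 10, count = 0, presence = 0),
    provenance = "pseudo-absence")), "outside")
})

test_that("extraction equals index arithmetic on random points", {
  lsc <- smallLandscape(17, rows = 30L, cols = 30L)
  st <- buildStack(lsc)
  set.seed(17)
  x <- runif(100, 0, 30 * 30 - 1e-6)
  y <- runif(100, 0, 30 * 30 - 1e-6)
  obs <- new("ObservationSet",
             points = data.frame(x = x, y = y, count = 0, presence = 0),
             provenance = "pseudo-absence")
  d <- extractAtPoints(st, obs)
  col <- floor(x / 30) + 1
  row <- floor(y / 30) + 1
  expect_equal(d$mnndvi, gridValues(stackLayers(st)$mnndvi)[cbind(row, col)])
  expect_equal(d$dist_ditch,
               gridValues(stackLayers(st)$dist_ditch)[cbind(row, col)])
})

test_that("rows with nodata predictors are dropped with a message", {
  lsc <- smallLandscape(18, rows = 10L, cols = 10L)
  mv <- gridValues(lsc@studyMask)
  mv[1, 1] <- 0  # invalidate one pixel
  lsc@studyMask <- gridLike(lsc@studyMask, mv)
  st <- buildStack(lsc)
  obs <- new("ObservationSet",
             points = data.frame(x = c(15, 45), y = c(15, 45),
                                 count = c(0, 0), presence = c(0, 0)),
             provenance = "pseudo-absence")
  expect_message(d <- extractAtPoints(st, obs), "dropped")
  expect_equal(nrow(d), 1L)
})
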