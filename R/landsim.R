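#' Configure the synthetic landscape generator
#'
#' Defaults emulate the structure of a ~2,200 km2 intensively farmed
#' coastal plain rasterized at 30 m: a rectangular study window of
#' 1560 x 1560 pixels (2,190 km2), about three quarters farmland, a dense
#' net of farmland roads and ditches, a few trunk roads, and five monthly
#' winter NDVI layers.
#'
#' @param rows,cols extent in pixels.
#' @param pixelSize pixel edge length in meters.
#' @param featureCounts named integer vector of feature counts per class
#'   (see [featureClasses()]); classes omitted default per `scaleFeatures`.
#' @param farmlandFraction proportion of pixels that are farmland.
#' @param ndviMonths number of monthly NDVI layers.
#' @param seed master seed for all generator randomness.
#' @param scaleFeatures if TRUE (default), default feature counts are
#'   scaled with the landscape area so small test landscapes keep the same
#'   relative feature density as the full-size default.
#' @return a \linkS4class{LandscapeConfig}.
#' @examples
#' cfg <- landscapeConfig(rows = 80, cols = 80, seed = 1)
#' @export
landscapeConfig <- function(rows = 1560L, cols = 1560L, pixelSize = 30,
                            featureCounts = integer(0),
                            farmlandFraction = 0.764, ndviMonths = 5L,
                            seed = 1L, scaleFeatures = TRUE) {
  # densities per full-size (1560^2) landscape
  full <- c(pools = 60L, rivers = 6L, residential = 120L,
            national_road = 2L, provincial_road = 3L, expressway = 1L,
            farmland_road = 60L, ditch = 30L)
  if (scaleFeatures) {
    area <- as.double(rows) * cols / (1560 * 1560)
    base <- pmax(ifelse(full > 0, 1L, 0L),
                 as.integer(round(full * sqrt(area))))
  } else base <- full
  base[names(featureCounts)] <- as.integer(featureCounts)
  new("LandscapeConfig", rows = as.integer(rows), cols = as.integer(cols),
      pixelSize = as.numeric(pixelSize),
      featureCounts = base[featureClasses()],
      farmlandFraction = as.numeric(farmlandFraction),
      ndviMonths = as.integer(ndviMonths), seed = as.integer(seed))
}

#' Configure the virtual species' habitat response
#'
#' Defaults reproduce plateau-shaped preference ranges of a wintering
#' farmland bird at full landscape scale: occurrence driven by farmland
#' patch area (0.6-7.5 km2), distance to residential (250-2,500 m),
#' distance to ditch (100-4,500 m) and distance to expressway
#' (6,000-19,000 m); abundance driven by a different subset — distance to
#' national road (2,300-9,500 m), distance to expressway (7,000-11,000 m),
#' distance to pool (> 1,500 m) and mean NDVI (> 0.13).
#'
#' @param occurrence,abundance data.frames with columns `predictor`,
#'   `low`, `high`, `penalty` defining plateau kernels.
#' @param lambdaMax expected flock size where all abundance kernels are 1.
#' @param dispersion count variance inflation factor (>= 1; 1 = Poisson).
#'   The default 8 yields mostly small flocks with occasional large ones.
#' @param nSites number of presence points to simulate (default 94).
#' @return a \linkS4class{ResponseConfig}.
#' @export
responseConfig <- function(occurrence = NULL, abundance = NULL,
                           lambdaMax = 40, dispersion = 8, nSites = 94L) {
  if (is.null(occurrence))
    occurrence <- data.frame(
      predictor = c("farmland_area", "dist_residential", "dist_ditch",
                    "dist_expressway"),
      low  = c(0.6, 250, 100, 6000),
      high = c(7.5, 2500, 4500, 19000),
      penalty = c(0.05, 0.2, 0.2, 0.2))
  if (is.null(abundance))
    abundance <- data.frame(
      predictor = c("dist_national_road", "dist_expressway", "dist_pools",
                    "mnndvi"),
      low  = c(2300, 7000, 1500, 0.13),
      high = c(9500, 11000, Inf, 1),
      penalty = c(0.2, 0.2, 0.1, 0.3))
  new("ResponseConfig", occurrence = occurrence, abundance = abundance,
      lambdaMax = as.numeric(lambdaMax), dispersion = as.numeric(dispersion),
      nSites = as.integer(nSites))
}

#' Demo virtual-species response for compact landscapes
#'
#' A response scaled to small (~3 km) landscapes, used throughout the
#' examples and the validation suite. Occurrence is dominated by high
#' mean winter NDVI (>= 0.20, a sharp preference occupying roughly a
#' tenth of the landscape) with a mild secondary preference for an
#' intermediate distance to residential areas; abundance is driven by a
#' different predictor pair (an intermediate distance band to the
#' national road and avoidance of the immediate vicinity of pools), so
#' occurrence and abundance patterns deliberately diverge, as they do for
#' real farmland birds.
#'
#' @param nSites number of presence points (default 94).
#' @param lambdaMax,dispersion count-model settings (defaults 40 and 8).
#' @return a \linkS4class{ResponseConfig}.
#' @export
demoResponseConfig <- function(nSites = 94L, lambdaMax = 40,
                               dispersion = 8) {
  responseConfig(
    occurrence = data.frame(
      predictor = c("mnndvi", "dist_residential"),
      low = c(0.20, 100), high = c(1, 1300), penalty = c(0.003, 0.05)),
    abundance = data.frame(
      predictor = c("dist_national_road", "dist_pools"),
      low = c(300, 200), high = c(1200, Inf), penalty = c(0.08, 0.3)),
    lambdaMax = lambdaMax, dispersion = dispersion, nSites = nSites)
}

# --- internal geometry helpers ---------------------------------------------

# rasterize discs (blobs) for areal features
placeBlobs <- function(rows, cols, n, rmin, rmax) {
  m <- matrix(0, rows, cols)
  if (n == 0L) return(m)
  cr <- sample.int(rows, n, replace = TRUE)
  cc <- sample.int(cols, n, replace = TRUE)
  rad <- stats::runif(n, rmin, rmax)
  for (i in seq_len(n)) {
    r0 <- max(1, floor(cr[i] - rad[i])); r1 <- min(rows, ceiling(cr[i] + rad[i]))
    c0 <- max(1, floor(cc[i] - rad[i])); c1 <- min(cols, ceiling(cc[i] + rad[i]))
    rr <- r0:r1; ccx <- c0:c1
    d2 <- outer((rr - cr[i])^2, (ccx - cc[i])^2, "+")
    m[rr, ccx][d2 <= rad[i]^2] <- 1
  }
  m
}

# rasterize a 1-pixel-wide polyline between successive vertices
rasterizeSegments <- function(m, vr, vc) {
  for (i in seq_len(length(vr) - 1)) {
    n <- max(abs(vr[i + 1] - vr[i]), abs(vc[i + 1] - vc[i])) * 2 + 1
    r <- round(seq(vr[i], vr[i + 1], length.out = n))
    c <- round(seq(vc[i], vc[i + 1], length.out = n))
    keep <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
    m[cbind(r[keep], c[keep])] <- 1
  }
  m
}

# random polyline crossing the full extent, with jittered waypoints
placePolylines <- function(rows, cols, n, wiggle) {
  m <- matrix(0, rows, cols)
  for (i in seq_len(n)) {
    horiz <- stats::runif(1) < 0.5
    nv <- 4L
    if (horiz) {
      vc <- round(seq(1, cols, length.out = nv))
      vr <- pmin(rows, pmax(1, round(stats::runif(1, 1, rows) +
        cumsum(c(0, stats::rnorm(nv - 1, 0, wiggle * rows))))))
    } else {
      vr <- round(seq(1, rows, length.out = nv))
      vc <- pmin(cols, pmax(1, round(stats::runif(1, 1, cols) +
        cumsum(c(0, stats::rnorm(nv - 1, 0, wiggle * cols))))))
    }
    m <- rasterizeSegments(m, vr, vc)
  }
  m
}

# spatially autocorrelated standard-normal-ish field via Gaussian
# smoothing; the kernel radius is capped so tiny grids remain valid
smoothField <- function(rows, cols, sigma) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  rad <- 2 * ceiling(3 * sigma) + 1
  maxOdd <- min(rows, cols) - (min(rows, cols) + 1) %% 2
  rad <- min(rad, maxOdd)
  if (rad >= 3) {
    z <- as.matrix(EBImage::gblur(z, sigma = sigma, radius = rad))
  }
  (z - mean(z)) / stats::sd(z)
}

# --- generator --------------------------------------------------------------

#' Generate a synthetic landscape
#'
#' Deterministic given `config@seed`: areal features (pools, residential)
#' are random discs, linear features (roads, rivers, ditches) random
#' 1-pixel polylines crossing the extent, farmland a thresholded smoothed
#' noise field covering `farmlandFraction` of the study area, and NDVI a
#' stack of spatially autocorrelated monthly fields clipped to `[-1, 1]`.
#'
#' @param config a \linkS4class{LandscapeConfig}.
#' @return a \linkS4class{Landscape}.
#' @export
generateLandscape <- function(config) {
  validObject(config)
  rows <- config@rows; cols <- config@cols
  if (as.double(rows) * cols < 1) stop("zero-area extent")
  npix <- as.double(rows) * cols
  if (any(config@featureCounts > npix))
    stop("requested feature count exceeds pixel count; cannot place")
  g0 <- function(v) grid(v, pixelSize = config@pixelSize, origin = c(0, 0))

  blobClasses <- c(pools = 1, residential = 2)
  blobRadii <- list(pools = c(1, 4), residential = c(3, 10))
  wiggles <- c(rivers = 0.06, national_road = 0.01, provincial_road = 0.01,
               expressway = 0.005, farmland_road = 0.02, ditch = 0.04)

  masks <- list()
  for (i in seq_along(featureClasses())) {
    cl <- featureClasses()[i]
    set.seed(childSeed(config@seed, i))
    n <- config@featureCounts[[cl]]
    m <- if (cl %in% names(blobClasses)) {
      r <- blobRadii[[cl]]
      placeBlobs(rows, cols, n, r[1], r[2])
    } else {
      placePolylines(rows, cols, n, wiggles[[cl]])
    }
    if (n > 0L && sum(m) == 0L)
      stop("failed to place any feature of class ", cl)
    masks[[cl]] <- g0(m)
  }

  set.seed(childSeed(config@seed, 20L))
  f <- config@farmlandFraction
  if (f >= 1) {
    farm <- matrix(1, rows, cols)
  } else if (f <= 0) {
    farm <- matrix(0, rows, cols)
  } else {
    field <- smoothField(rows, cols, sigma = max(2, min(rows, cols) / 30))
    thr <- stats::quantile(field, 1 - f, names = FALSE)
    farm <- (field > thr) + 0
  }

  # winter vegetation pattern persists across months: each month is a
  # shared base field plus month-specific noise
  set.seed(childSeed(config@seed, 29L))
  ndviBase <- smoothField(rows, cols, sigma = 3)
  ndvi <- vector("list", config@ndviMonths)
  for (mth in seq_len(config@ndviMonths)) {
    set.seed(childSeed(config@seed, 30L + mth))
    z <- 0.14 + 0.05 * (sqrt(0.7) * ndviBase +
                          sqrt(0.3) * smoothField(rows, cols, sigma = 3))
    z[z > 1] <- 1
    z[z < -1] <- -1
    ndvi[[mth]] <- g0(z)
  }
  names(ndvi) <- paste0("month_", seq_len(config@ndviMonths))

  new("Landscape", featureMasks = masks, farmland = g0(farm), ndvi = ndvi,
      studyMask = g0(matrix(1, rows, cols)), config = config)
}

# evaluate one plateau kernel table over a stack; product across rows
plateauProduct <- function(stack, tab) {
  ref <- stack@layers[[1]]
  out <- matrix(1, nrow(ref@values), ncol(ref@values))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$predictor[i]
    if (!nm %in% names(stack@layers))
      stop("response references unknown predictor: ", nm)
    v <- stack@layers[[nm]]@values
    k <- ifelse(v >= tab$low[i] & v <= tab$high[i], 1, tab$penalty[i])
    out <- out * k
  }
  out
}

#' Ground-truth occurrence and abundance surfaces
#'
#' Evaluates the virtual species' response pixel-wise: occurrence
#' probability `p` is the product of the occurrence plateau kernels
#' rescaled to maximum 1 over the landscape, expected count `lambda` is
#' `lambdaMax` times the product of the abundance kernels.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param response a \linkS4class{ResponseConfig}.
#' @param stack optionally, a pre-built \linkS4class{PredictorStack} for
#'   `landscape` (rebuilt if missing).
#' @return list with Grids `p` (in `[0, 1]`) and `lambda` (>= 0).
#' @export
trueSurfaces <- function(landscape, response, stack = NULL) {
  validObject(response)
  if (is.null(stack)) stack <- buildStack(landscape)
  ref <- stack@layers[[1]]
  p <- plateauProduct(stack, response@occurrence)
  mx <- max(p, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) p <- p / mx
  lam <- response@lambdaMax * plateauProduct(stack, response@abundance)
  list(p = gridLike(ref, p), lambda = gridLike(ref, lam))
}

# negative-binomial count with mean mu and variance dispersion * mu,
# truncated to >= 1 (flocks observed at a presence site are non-empty)
rTruncCount <- function(n, mu, dispersion) {
  draw <- function(idx) {
    m <- mu[idx]
    if (dispersion <= 1 + 1e-12) stats::rpois(length(idx), m)
    else stats::rnbinom(length(idx), mu = m, size = m / (dispersion - 1))
  }
  mu <- pmax(mu, 1e-9)
  x <- draw(seq_len(n))
  for (it in 1:100) {
    z <- which(x == 0)
    if (!length(z)) break
    x[z] <- draw(z)
  }
  pmax(x, 1L)
}

#' Simulate flock observations of the virtual species
#'
#' Draws `nSites` distinct presence pixels with probability proportional
#' to the true occurrence surface `p`, then a flock count at each from a
#' negative binomial with mean `lambda` at that pixel and variance
#' `dispersion * lambda`, truncated to at least 1. Points are placed at
#' pixel centers. Deterministic given `seed`.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param response a \linkS4class{ResponseConfig}.
#' @param seed integer seed.
#' @param stack optional pre-built \linkS4class{PredictorStack}.
#' @return an \linkS4class{ObservationSet} with provenance "synthetic".
#' @export
simulateObservations <- function(landscape, response, seed, stack = NULL) {
  surf <- trueSurfaces(landscape, response, stack)
  p <- surf$p@values
  valid <- which(!is.na(p) & landscape@studyMask@values == 1 & p > 0)
  if (!length(valid)) stop("occurrence probability is identically zero")
  n <- response@nSites
  if (n > length(valid))
    stop("nSites exceeds the number of valid pixels with positive p")
  set.seed(childSeed(seed, 50L))
  idx <- sample(valid, n, prob = p[valid])
  rc <- arrayInd(idx, dim(p))
  g <- surf$p
  s <- g@pixelSize
  x <- g@origin[1] + (rc[, 2] - 0.5) * s
  y <- g@origin[2] + (rc[, 1] - 0.5) * s
  lam <- surf$lambda@values[idx]
  set.seed(childSeed(seed, 51L))
  counts <- rTruncCount(n, lam, response@dispersion)
  new("ObservationSet",
      points = data.frame(x = x, y = y, count = as.numeric(counts),
                          presence = 1),
      provenance = "synthetic")
}

setMethod("show", "ObservationSet", function(object) {
  p <- object@points
  cat(sprintf("ObservationSet (%s): %d points, %d presences\n",
              object@provenance, nrow(p), sum(p$presence == 1)))
  if (any(p$presence == 1))
    cat(sprintf("  counts: median %g, max %g\n",
                stats::median(p$count[p$presence == 1]),
                max(p$count)))
})

#' @describeIn simulateObservations accessor for the point table.
#' @param x an ObservationSet.
#' @export
observations <- function(x) x@points

# --- external interfaces ----------------------------------------------------

#' Write / read observation points as CSV
#'
#' Columns `x`, `y`, `count`, `presence`; coordinates in projected meters,
#' pixel-center convention.
#'
#' @param obs an \linkS4class{ObservationSet}.
#' @param path CSV path.
#' @return `path` / an ObservationSet.
#' @export
writeObservations <- function(obs, path) {
  utils::write.csv(obs@points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeObservations
#' @param provenance provenance tag for the points read.
#' @export
readObservations <- function(path, provenance = "field") {
  p <- utils::read.csv(path)
  if (is.null(p$presence)) p$presence <- as.integer(p$count > 0)
  new("ObservationSet", points = p, provenance = provenance)
}

#' Write a Landscape to a directory of ASCII grids
#'
#' One `.asc` per feature mask, the farmland mask, the study mask, and
#' each monthly NDVI layer.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
writeLandscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(g, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsciiGrid(g, p)
    p
  }
  for (cl in names(landscape@featureMasks))
    paths <- c(paths, wr(landscape@featureMasks[[cl]], paste0("mask_", cl)))
  paths <- c(paths, wr(landscape@farmland, "farmland"),
             wr(landscape@studyMask, "study_mask"))
  for (nm in names(landscape@ndvi))
    paths <- c(paths, wr(landscape@ndvi[[nm]], paste0("ndvi_", nm)))
  invisible(paths)
}

#' Write / read generator configuration as YAML
#'
#' Mirrors the \linkS4class{LandscapeConfig} and
#' \linkS4class{ResponseConfig} fields.
#'
#' @param landscapeCfg a LandscapeConfig.
#' @param responseCfg a ResponseConfig.
#' @param path YAML file path.
#' @return `path` / a list with elements `landscape` and `response`.
#' @export
writeSimConfig <- function(landscapeCfg, responseCfg, path) {
  obj <- list(
    landscape = list(rows = landscapeCfg@rows, cols = landscapeCfg@cols,
                     pixel_size = landscapeCfg@pixelSize,
                     feature_counts = as.list(landscapeCfg@featureCounts),
                     farmland_fraction = landscapeCfg@farmlandFraction,
                     ndvi_months = landscapeCfg@ndviMonths,
                     seed = landscapeCfg@seed),
    response = list(occurrence = responseCfg@occurrence,
                    abundance = responseCfg@abundance,
                    lambda_max = responseCfg@lambdaMax,
                    dispersion = responseCfg@dispersion,
                    n_sites = responseCfg@nSites))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  lc <- obj$landscape
  rc <- obj$response
  cols <- c("predictor", "low", "high", "penalty")
  asPlateau <- function(x) {
    if (is.data.frame(x)) return(x[cols])
    if (all(cols %in% names(x)))         # column-major (yaml data.frame)
      return(data.frame(predictor = as.character(x$predictor),
                        low = as.numeric(x$low), high = as.numeric(x$high),
                        penalty = as.numeric(x$penalty)))
    data.frame(                          # list of row records
      predictor = vapply(x, function(e) as.character(e$predictor), ""),
      low = vapply(x, function(e) as.numeric(e$low), 0),
      high = vapply(x, function(e) as.numeric(e$high), 0),
      penalty = vapply(x, function(e) as.numeric(e$penalty), 0))
  }
  list(
    landscape = landscapeConfig(
      rows = lc$rows, cols = lc$cols, pixelSize = lc$pixel_size,
      featureCounts = unlist(lc$feature_counts),
      farmlandFraction = lc$farmland_fraction,
      ndviMonths = lc$ndvi_months, seed = lc$seed, scaleFeatures = FALSE),
    response = responseConfig(
      occurrence = asPlateau(rc$occurrence),
      abundance = asPlateau(rc$abundance),
      lambdaMax = rc$lambda_max, dispersion = rc$dispersion,
      nSites = rc$n_sites))
}
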