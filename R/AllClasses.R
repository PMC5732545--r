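#' @import methods
NULL

#' Grid: a single-band georeferenced raster
#'
#' The universal spatial carrier of the package: a rectangular matrix of
#' values with a pixel size in meters, the world coordinate of the top-left
#' corner, and `NA` marking nodata pixels.
#'
#' Coordinate convention (fixed across the package): the origin `(x0, y0)`
#' is the top-left corner of the top-left pixel; x grows eastward along
#' columns, y grows southward along rows. Pixels are half-open,
#' `[x0 + c*s, x0 + (c+1)*s)` horizontally and likewise vertically, so a
#' point on a shared edge belongs to the pixel to the right/below. All
#' distances are measured center to center.
#'
#' @slot values numeric matrix; `NA` is nodata.
#' @slot pixelSize positive scalar, pixel edge length in meters.
#' @slot origin numeric length-2, world `(x0, y0)` of the top-left corner.
#'
#' @aliases Grid-class
#' @exportClass Grid
setClass("Grid",
  representation(values = "matrix", pixelSize = "numeric", origin = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), pixelSize = 30,
            origin = c(0, 0)))

setValidity("Grid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite numbers (x0, y0)")
  if (length(msg)) msg else TRUE
})

#' ObservationSet: point observations of flocks
#'
#' Presence points carry a positive flock count; pseudo-absence
#' (background) points have presence 0 and count 0. Coordinates are in
#' projected meters under the package's grid convention (see
#' \linkS4class{Grid}).
#'
#' @slot points data.frame with columns `x`, `y`, `count`, `presence`.
#' @slot provenance one of "field", "synthetic", "pseudo-absence", "mixed".
#'
#' @aliases ObservationSet-class
#' @exportClass ObservationSet
setClass("ObservationSet",
  representation(points = "data.frame", provenance = "character"))

setValidity("ObservationSet", function(object) {
  p <- object@points
  need <- c("x", "y", "count", "presence")
  if (!all(need %in% names(p)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (any(!p$presence %in% c(0, 1)))
    return("presence must be 0 or 1")
  if (any(p$count < 0))
    return("counts must be non-negative")
  if (object@provenance %in% c("field", "synthetic") &&
      any(p$presence == 1 & p$count < 1))
    return("presence points must have count >= 1")
  if (any(p$presence == 0 & p$count != 0))
    return("absence points must have count 0")
  TRUE
})

#' LandscapeConfig: parameters of the synthetic landscape generator
#'
#' @slot rows,cols extent in pixels.
#' @slot pixelSize pixel edge length in meters (default 30).
#' @slot featureCounts named integer vector: number of features to place per
#'   class (pools, rivers, residential, national_road, provincial_road,
#'   expressway, farmland_road, ditch).
#' @slot farmlandFraction proportion of the study area that is farmland,
#'   in `[0, 1]`.
#' @slot ndviMonths number of monthly NDVI layers (>= 1).
#' @slot seed master seed; every downstream random draw derives from it.
#'
#' @aliases LandscapeConfig-class
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(rows = "integer", cols = "integer", pixelSize = "numeric",
                 featureCounts = "integer", farmlandFraction = "numeric",
                 ndviMonths = "integer", seed = "integer"))

setValidity("LandscapeConfig", function(object) {
  msg <- character(0)
  if (object@rows < 1L || object@cols < 1L)
    msg <- c(msg, "rows and cols must be >= 1")
  if (object@farmlandFraction < 0 || object@farmlandFraction > 1)
    msg <- c(msg, "farmlandFraction must be in [0, 1]")
  if (object@ndviMonths < 1L)
    msg <- c(msg, "ndviMonths must be >= 1")
  if (!setequal(names(object@featureCounts), featureClasses()))
    msg <- c(msg, paste("featureCounts must be named exactly:",
                        paste(featureClasses(), collapse = ", ")))
  if (any(object@featureCounts < 0L))
    msg <- c(msg, "feature counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ResponseConfig: the virtual species' habitat response
#'
#' Occurrence probability is a product of per-predictor plateau kernels
#' (value 1 inside `[low, high]`, `penalty` outside), rescaled so its
#' maximum over the landscape is 1. Expected abundance is
#' `lambdaMax` times an analogous product over a (possibly different)
#' predictor subset. Counts at presence sites are drawn from a negative
#' binomial with mean lambda and variance `dispersion * lambda`,
#' truncated to be at least 1.
#'
#' @slot occurrence data.frame with columns `predictor`, `low`, `high`,
#'   `penalty` — the occurrence plateaus.
#' @slot abundance data.frame with the same columns — the abundance plateaus.
#' @slot lambdaMax expected count where all abundance kernels are at 1.
#' @slot dispersion variance inflation factor (>= 1; 1 = Poisson).
#' @slot nSites number of presence points to simulate.
#'
#' @aliases ResponseConfig-class
#' @exportClass ResponseConfig
setClass("ResponseConfig",
  representation(occurrence = "data.frame", abundance = "data.frame",
                 lambdaMax = "numeric", dispersion = "numeric",
                 nSites = "integer"))

setValidity("ResponseConfig", function(object) {
  msg <- character(0)
  for (tab in list(object@occurrence, object@abundance)) {
    if (!all(c("predictor", "low", "high", "penalty") %in% names(tab)))
      msg <- c(msg, "plateau tables need predictor, low, high, penalty")
    else {
      if (any(tab$low >= tab$high))
        msg <- c(msg, "plateau edges must satisfy low < high")
      if (any(tab$penalty < 0 | tab$penalty > 1))
        msg <- c(msg, "penalty must be in [0, 1]")
    }
  }
  if (object@lambdaMax < 0) msg <- c(msg, "lambdaMax must be >= 0")
  if (object@dispersion < 1) msg <- c(msg, "dispersion must be >= 1")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (length(msg)) unique(msg) else TRUE
})

#' Landscape: the synthetic study system
#'
#' @slot featureMasks named list of binary \linkS4class{Grid}s, one per
#'   feature class.
#' @slot farmland binary farmland mask Grid.
#' @slot ndvi list of monthly NDVI Grids, values in `[-1, 1]`.
#' @slot studyMask binary validity mask Grid.
#' @slot config the \linkS4class{LandscapeConfig} that generated it.
#'
#' @aliases Landscape-class
#' @exportClass Landscape
setClass("Landscape",
  representation(featureMasks = "list", farmland = "Grid", ndvi = "list",
                 studyMask = "Grid", config = "LandscapeConfig"))

setValidity("Landscape", function(object) {
  msg <- character(0)
  grids <- c(object@featureMasks, list(object@farmland, object@studyMask),
             object@ndvi)
  ref <- grids[[1]]
  for (g in grids)
    if (!gridsAligned(ref, g)) { msg <- c(msg, "all Grids must be aligned"); break }
  for (g in c(object@featureMasks, list(object@farmland, object@studyMask))) {
    v <- g@values
    if (any(!v[!is.na(v)] %in% c(0, 1))) { msg <- c(msg, "masks must be binary"); break }
  }
  for (g in object@ndvi) {
    v <- g@values
    if (any(v[!is.na(v)] < -1 | v[!is.na(v)] > 1)) {
      msg <- c(msg, "NDVI must lie in [-1, 1]"); break
    }
  }
  if (!setequal(names(object@featureMasks), featureClasses()))
    msg <- c(msg, "featureMasks must cover every feature class")
  if (length(msg)) msg else TRUE
})

#' PredictorStack: the aligned habitat predictor layers
#'
#' An ordered, named collection of aligned \linkS4class{Grid}s holding the
#' eleven habitat variables: eight distance-to-feature layers (meters),
#' farmland patch area (square kilometers), and the mean and maximum NDVI
#' over the wintering months (MNNDVI, MAXNDVI; unitless).
#'
#' @slot layers named list of Grids.
#'
#' @aliases PredictorStack-class
#' @exportClass PredictorStack
setClass("PredictorStack", representation(layers = "list"))

setValidity("PredictorStack", function(object) {
  if (length(object@layers) == 0L) return("stack is empty")
  nm <- names(object@layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    return("layers must have unique non-empty names")
  ref <- object@layers[[1]]
  for (g in object@layers) {
    if (!is(g, "Grid")) return("every layer must be a Grid")
    if (!gridsAligned(ref, g)) return("layers must share extent, pixel size and origin")
  }
  TRUE
})

#' OccurrenceFit: a fitted occurrence (presence/background) model
#'
#' @slot forest the fitted randomForest classifier.
#' @slot training the training sample matrix (data.frame).
#' @slot predictors predictor column names used in training.
#' @slot oobScores out-of-bag presence vote fraction per training point.
#' @slot nTrees,seed fit settings.
#' @slot classWeights named class weights used (balanced: N / (2 N_c)).
#'
#' @aliases OccurrenceFit-class
#' @exportClass OccurrenceFit
setClass("OccurrenceFit",
  representation(forest = "ANY", training = "data.frame",
                 predictors = "character", oobScores = "numeric",
                 nTrees = "integer", classWeights = "numeric",
                 seed = "integer"))

#' AbundanceFit: a fitted abundance (count regression) model
#'
#' @slot forest the fitted randomForest regressor.
#' @slot training the training sample matrix (data.frame).
#' @slot predictors the selected predictor names.
#' @slot oobPredictions out-of-bag predicted count per training point.
#' @slot nTrees,seed fit settings.
#'
#' @aliases AbundanceFit-class
#' @exportClass AbundanceFit
setClass("AbundanceFit",
  representation(forest = "ANY", training = "data.frame",
                 predictors = "character", oobPredictions = "numeric",
                 nTrees = "integer", seed = "integer"))

#' AdjustmentFit: the linear abundance calibration
#'
#' Ordinary least squares of observed counts on predicted counts:
#' adjusted = A * predicted + B, with fit quality R-squared.
#'
#' @slot A slope (unitless).
#' @slot B intercept (count units).
#' @slot rSquared coefficient of determination in `[0, 1]`.
#' @slot n number of pairs used.
#'
#' @aliases AdjustmentFit-class
#' @exportClass AdjustmentFit
setClass("AdjustmentFit",
  representation(A = "numeric", B = "numeric", rSquared = "numeric",
                 n = "integer"))

setValidity("AdjustmentFit", function(object) {
  if (!is.finite(object@A) || !is.finite(object@B))
    return("A and B must be finite")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    return("rSquared must be in [0, 1]")
  TRUE
})

#' SurfaceBundle: the exportable prediction surfaces
#'
#' @slot rio relative index of occurrence Grid, values in `[0, 1]`.
#' @slot raRaw raw predicted abundance Grid.
#' @slot raAdjusted adjusted abundance Grid (>= 0).
#' @slot pi priority protection index Grid in `[0, 1]`, max 1.
#'
#' @aliases SurfaceBundle-class
#' @exportClass SurfaceBundle
setClass("SurfaceBundle",
  representation(rio = "Grid", raRaw = "Grid", raAdjusted = "Grid",
                 pi = "Grid"))

setValidity("SurfaceBundle", function(object) {
  grids <- list(object@rio, object@raRaw, object@raAdjusted, object@pi)
  ref <- grids[[1]]
  for (g in grids)
    if (!gridsAligned(ref, g)) return("surfaces must be aligned")
  rio <- object@rio@values
  if (any(rio[!is.na(rio)] < 0 | rio[!is.na(rio)] > 1))
    return("RIO must lie in [0, 1]")
  ra <- object@raAdjusted@values
  if (any(ra[!is.na(ra)] < 0))
    return("adjusted RA must be >= 0")
  piv <- object@pi@values[!is.na(object@pi@values)]
  if (length(piv) && (min(piv) < 0 || max(piv) > 1 + 1e-12))
    return("PI must lie in [0, 1]")
  TRUE
})

#' IdwParams: inverse-distance-weighting settings
#'
#' @slot power distance exponent p > 0 (default 2).
#' @slot k number of nearest neighbours (default 12).
#'
#' @aliases IdwParams-class
#' @exportClass IdwParams
setClass("IdwParams", representation(power = "numeric", k = "integer"))

setValidity("IdwParams", function(object) {
  if (object@power <= 0) return("power must be > 0")
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' RelationCurve: binned occurrence-abundance relation
#'
#' @slot curve data.frame with `rio_bin_center`, `mean_observed_count`,
#'   `n_points` per equal-width RIO bin on `[0, 1]`.
#' @slot scatter data.frame with per-point `rio` and `count`.
#'
#' @aliases RelationCurve-class
#' @exportClass RelationCurve
setClass("RelationCurve",
  representation(curve = "data.frame", scatter = "data.frame"))
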