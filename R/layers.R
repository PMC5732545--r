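#' Euclidean distance to the nearest feature pixel
#'
#' Exact center-to-center Euclidean distance transform: every pixel holds
#' the distance in meters from its center to the center of the nearest
#' feature (value 1) pixel; feature pixels hold 0. Nodata pixels are never
#' treated as features and stay nodata in the output.
#'
#' @param featureMask a binary \linkS4class{Grid} with at least one
#'   feature pixel.
#' @return a \linkS4class{Grid} of distances in meters.
#' @examples
#' m <- matrix(0, 5, 6); m[1, 1] <- 1
#' d <- distanceLayer(grid(m, pixelSize = 30))
#' gridValues(d)[4, 5]  # 3-4-5 triangle: 150 m
#' @export
distanceLayer <- function(featureMask) {
  v <- featureMask@values
  feat <- !is.na(v) & v == 1
  if (!any(feat)) stop("feature mask is empty: no feature pixels")
  bg <- matrix(1, nrow(v), ncol(v))
  bg[feat] <- 0
  d <- as.matrix(EBImage::imageData(EBImage::distmap(bg, metric = "euclidean")))
  d <- d * featureMask@pixelSize
  d[is.na(v)] <- NA
  gridLike(featureMask, d)
}

#' Area of the connected farmland patch at each pixel
#'
#' Labels farmland pixels into 4-connected patches and assigns every
#' farmland pixel the total area of its patch in square kilometers.
#' Non-farmland pixels carry 0 (so background points off farmland remain
#' usable); nodata propagates.
#'
#' @param farmlandMask a binary \linkS4class{Grid}.
#' @return a \linkS4class{Grid} of patch areas in km2.
#' @export
farmlandPatchArea <- function(farmlandMask) {
  v <- farmlandMask@values
  m <- v
  m[is.na(m)] <- 0
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(m)))
  out <- matrix(0, nrow(v), ncol(v))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    pixArea <- farmlandMask@pixelSize^2 / 1e6
    out[lab > 0] <- sizes[lab[lab > 0]] * pixArea
  }
  out[is.na(v)] <- NA
  gridLike(farmlandMask, out)
}

#' Pixel-wise NDVI summaries over months
#'
#' Mean (MNNDVI) and maximum (MAXNDVI) over the monthly layers, computed
#' over the months available at each pixel; a pixel is nodata only where
#' every month is nodata.
#'
#' @param ndviStack list of aligned NDVI \linkS4class{Grid}s.
#' @return list with Grids `mean` and `max`.
#' @export
ndviSummaries <- function(ndviStack) {
  stopifnot(length(ndviStack) >= 1L)
  ref <- ndviStack[[1]]
  for (g in ndviStack)
    if (!gridsAligned(ref, g)) stop("NDVI layers are misaligned")
  arr <- vapply(ndviStack, function(g) g@values,
                matrix(0, nrow(ref@values), ncol(ref@values)))
  dim(arr) <- c(length(ref@values), length(ndviStack))
  nAvail <- rowSums(!is.na(arr))
  mn <- rowMeans(arr, na.rm = TRUE)
  mx <- suppressWarnings(apply(arr, 1, max, na.rm = TRUE))
  mn[nAvail == 0] <- NA
  mx[nAvail == 0] <- NA
  shape <- function(x) matrix(x, nrow(ref@values), ncol(ref@values))
  list(mean = gridLike(ref, shape(mn)), max = gridLike(ref, shape(mx)))
}

#' Build the eleven-layer habitat predictor stack
#'
#' Composes [distanceLayer()] over each feature class,
#' [farmlandPatchArea()] over the farmland mask, and [ndviSummaries()]
#' over the NDVI months into the canonical aligned stack (see
#' [predictorNames()]). Pixels outside the study mask are nodata in every
#' layer.
#'
#' @param landscape a \linkS4class{Landscape}.
#' @return a \linkS4class{PredictorStack}.
#' @export
buildStack <- function(landscape) {
  missing <- setdiff(featureClasses(), names(landscape@featureMasks))
  if (length(missing))
    stop("landscape lacks feature class(es): ", paste(missing, collapse = ", "))
  layers <- list()
  for (cl in featureClasses())
    layers[[paste0("dist_", cl)]] <- distanceLayer(landscape@featureMasks[[cl]])
  layers[["farmland_area"]] <- farmlandPatchArea(landscape@farmland)
  s <- ndviSummaries(landscape@ndvi)
  layers[["mnndvi"]] <- s$mean
  layers[["maxndvi"]] <- s$max
  outside <- landscape@studyMask@values != 1
  if (any(outside, na.rm = TRUE) || anyNA(landscape@studyMask@values)) {
    bad <- outside | is.na(landscape@studyMask@values)
    layers <- lapply(layers, function(g) {
      g@values[bad] <- NA
      g
    })
  }
  new("PredictorStack", layers = layers[predictorNames()])
}

#' @describeIn buildStack the named list of layer Grids.
#' @param x a PredictorStack.
#' @export
stackLayers <- function(x) x@layers

setMethod("show", "PredictorStack", function(object) {
  ref <- object@layers[[1]]
  cat(sprintf("PredictorStack: %d layers, %d x %d pixels @ %g m\n",
              length(object@layers), nrow(ref@values), ncol(ref@values),
              ref@pixelSize))
  cat("  ", paste(names(object@layers), collapse = ", "), "\n")
})

#' Extract predictor values at observation points
#'
#' Looks up, for every point, the value of the pixel containing it in
#' every layer (half-open pixel convention, see \linkS4class{Grid}).
#' Rows with any nodata predictor are dropped and the count of dropped
#' rows reported via `message()`.
#'
#' @param stack a \linkS4class{PredictorStack}.
#' @param points an \linkS4class{ObservationSet}; all points must fall
#'   inside the grid extent.
#' @return the sample matrix: a data.frame with `id`, one column per
#'   predictor, plus `presence` and `count`.
#' @export
extractAtPoints <- function(stack, points) {
  ref <- stack@layers[[1]]
  p <- points@points
  cell <- pointToCell(ref, p$x, p$y)
  idx <- cbind(cell$row, cell$col)
  out <- data.frame(id = seq_len(nrow(p)))
  for (nm in names(stack@layers))
    out[[nm]] <- stack@layers[[nm]]@values[idx]
  out$presence <- p$presence
  out$count <- p$count
  keep <- stats::complete.cases(out[names(stack@layers)])
  if (any(!keep))
    message(sum(!keep), " point(s) dropped for nodata predictor values")
  out[keep, , drop = FALSE]
}
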