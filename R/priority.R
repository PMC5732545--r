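#' @useDynLib sdmPriority, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Inverse-distance-weighting settings
#'
#' @param power distance exponent p > 0 (default 2).
#' @param k number of nearest neighbours (default 12). Both defaults are
#'   common GIS choices and are exposed because the appropriate smoothing
#'   radius depends on the sampling density.
#' @return an \linkS4class{IdwParams}.
#' @export
idwParams <- function(power = 2, k = 12L) {
  new("IdwParams", power = as.numeric(power), k = as.integer(k))
}

#' Compute the priority protection index (PI)
#'
#' Pixel-wise fusion of the occurrence and abundance surfaces:
#' `PI = (RIO * RA) / max(RIO * RA)`, the maximum taken over valid
#' pixels, yielding an index from 0 to 1 that ranks pixels for
#' conservation. RA here is conventionally the adjusted abundance.
#'
#' @param rio occurrence-index \linkS4class{Grid}, values in `[0, 1]`.
#' @param ra abundance \linkS4class{Grid}, values >= 0.
#' @return the PI \linkS4class{Grid}; nodata where either input is nodata.
#'   Errors if every product is zero (the index is then undefined, 0/0,
#'   and an all-zero map would silently read as "no priority anywhere").
#' @examples
#' rio <- grid(matrix(c(0.5, 1), 1)); ra <- grid(matrix(c(10, 20), 1))
#' gridValues(computePI(rio, ra))  # 0.25, 1
#' @export
computePI <- function(rio, ra) {
  if (!gridsAligned(rio, ra)) stop("rio and ra are not aligned")
  rv <- rio@values
  av <- ra@values
  if (any(rv[!is.na(rv)] < 0 | rv[!is.na(rv)] > 1))
    stop("RIO must lie in [0, 1]")
  if (any(av[!is.na(av)] < 0))
    stop("RA must be >= 0")
  prod <- rv * av
  m <- suppressWarnings(max(prod, na.rm = TRUE))
  if (!is.finite(m) || m <= 0)
    stop("all RIO * RA products are zero; PI is undefined")
  gridLike(rio, prod / m)
}

#' Smooth point values onto a grid by inverse distance weighting
#'
#' At each target pixel center, the weighted mean of the `k` nearest
#' sample values with weights `d^(-power)`; a pixel coinciding with a
#' sample point takes that sample's value exactly. Output therefore lies
#' within the range of the sample values.
#'
#' @param points data.frame with columns `x`, `y`, `value`.
#' @param params an \linkS4class{IdwParams}.
#' @param target a \linkS4class{Grid} template supplying the output
#'   lattice (values ignored; nodata pixels stay nodata).
#' @return a \linkS4class{Grid}.
#' @export
idwSmooth <- function(points, params = idwParams(), target) {
  validObject(params)
  if (!nrow(points)) stop("no points to interpolate")
  if (params@k > nrow(points))
    stop("k exceeds the number of points")
  ctr <- pixelCenters(target)
  out <- .idwGrid(points$x, points$y, points$value, ctr$x, ctr$y,
                  params@k, params@power)
  out[is.na(target@values)] <- NA
  gridLike(target, out)
}

#' Smooth a Grid's own pixel values (cosmetic mapping step)
#'
#' Convenience wrapper: treats every valid pixel center of `g` as a
#' sample point and re-interpolates onto the same lattice with
#' [idwSmooth()]. With the exact-interpolation property this is the
#' identity at sample pixels; it fills nodata-free lattices smoothly when
#' mapping at a different resolution.
#'
#' @param g a \linkS4class{Grid}.
#' @param params an \linkS4class{IdwParams}.
#' @param target optional output template (defaults to `g`).
#' @return a \linkS4class{Grid}.
#' @export
idwSmoothGrid <- function(g, params = idwParams(), target = g) {
  ctr <- pixelCenters(g)
  v <- g@values
  ok <- which(!is.na(v), arr.ind = TRUE)
  pts <- data.frame(x = ctr$x[ok[, 2]], y = ctr$y[ok[, 1]],
                    value = v[ok])
  idwSmooth(pts, params, target)
}

#' Assemble a surface bundle
#'
#' @param rio,raRaw,raAdjusted,pi aligned \linkS4class{Grid}s (see
#'   \linkS4class{SurfaceBundle}).
#' @return a \linkS4class{SurfaceBundle}.
#' @export
surfaceBundle <- function(rio, raRaw, raAdjusted, pi) {
  new("SurfaceBundle", rio = rio, raRaw = raRaw, raAdjusted = raAdjusted,
      pi = pi)
}

setMethod("show", "SurfaceBundle", function(object) {
  d <- dim(object@rio@values)
  cat(sprintf("SurfaceBundle: %d x %d pixels\n", d[1], d[2]))
  pr <- function(nm, g) {
    v <- g@values[!is.na(g@values)]
    cat(sprintf("  %-12s [%g, %g]\n", nm, min(v), max(v)))
  }
  pr("RIO", object@rio); pr("RA raw", object@raRaw)
  pr("RA adjusted", object@raAdjusted); pr("PI", object@pi)
})

#' Export a surface bundle to disk
#'
#' Writes `rio.asc`, `ra_raw.asc`, `ra_adjusted.asc` and `pi.asc`
#' (full-precision ASCII grids) plus a `provenance.json` sidecar holding
#' the maximum RIO*RA product used to normalize PI and any metadata
#' passed in `meta`.
#'
#' @param bundle a \linkS4class{SurfaceBundle}.
#' @param outDir output directory (created if needed).
#' @param meta named list merged into the sidecar (seeds, settings, ...).
#' @return named character vector of file paths, invisibly.
#' @export
exportBundle <- function(bundle, outDir, meta = list()) {
  validObject(bundle)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(rio = "rio.asc", ra_raw = "ra_raw.asc",
             ra_adjusted = "ra_adjusted.asc", pi = "pi.asc")
  grids <- list(rio = bundle@rio, ra_raw = bundle@raRaw,
                ra_adjusted = bundle@raAdjusted, pi = bundle@pi)
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(outDir, files[[nm]])
    writeAsciiGrid(grids[[nm]], p)
    paths[nm] <- p
  }
  prod <- bundle@rio@values * bundle@raAdjusted@values
  sidecar <- c(list(
    max_rio_ra = max(prod, na.rm = TRUE),
    pixel_size = bundle@rio@pixelSize,
    origin = bundle@rio@origin,
    dim = dim(bundle@rio@values),
    axis_note = "y grows southward from origin (top-left corner)"),
    meta)
  sp <- file.path(outDir, "provenance.json")
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["provenance"] <- sp
  invisible(paths)
}
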