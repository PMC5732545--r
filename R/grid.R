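#' Construct a Grid
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param pixelSize pixel edge length in meters.
#' @param origin world coordinate `(x0, y0)` of the top-left corner
#'   (x grows eastward, y grows southward; see \linkS4class{Grid}).
#' @return a \linkS4class{Grid}.
#' @examples
#' g <- grid(matrix(1:6, 2, 3), pixelSize = 30)
#' dim(gridValues(g))
#' @export
grid <- function(values, pixelSize = 30, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("Grid", values = values, pixelSize = as.numeric(pixelSize),
      origin = as.numeric(origin))
}

#' @describeIn grid the value matrix (NA = nodata).
#' @param x a Grid.
#' @export
gridValues <- function(x) x@values

#' @describeIn grid the pixel size in meters.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn grid the world `(x0, y0)` of the top-left corner.
#' @export
gridOrigin <- function(x) x@origin

#' @describeIn grid a Grid with the same georeferencing but new values.
#' @param template a Grid supplying georeferencing.
#' @export
gridLike <- function(template, values) {
  grid(values, pixelSize = template@pixelSize, origin = template@origin)
}

#' Do two grids share extent, pixel size and origin?
#'
#' @param a,b Grids.
#' @return logical.
#' @export
gridsAligned <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@pixelSize, b@pixelSize)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

setMethod("show", "Grid", function(object) {
  d <- dim(object@values)
  cat(sprintf("Grid: %d x %d pixels @ %g m, origin (%g, %g)\n",
              d[1], d[2], object@pixelSize, object@origin[1],
              object@origin[2]))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(object@values))))
  else cat("  all nodata\n")
})

#' World coordinates of pixel centers
#'
#' @param g a Grid.
#' @return list with vectors `x` (per column) and `y` (per row) of pixel
#'   center coordinates.
#' @export
pixelCenters <- function(g) {
  s <- g@pixelSize
  list(x = g@origin[1] + (seq_len(ncol(g@values)) - 0.5) * s,
       y = g@origin[2] + (seq_len(nrow(g@values)) - 0.5) * s)
}

#' Map world points to pixel row/column indices
#'
#' Applies the package's half-open pixel convention: a point on a shared
#' edge belongs to the pixel to the right/below.
#'
#' @param g a Grid.
#' @param x,y world coordinates in meters.
#' @return data.frame with 1-based `row` and `col`.
#' @export
pointToCell <- function(g, x, y) {
  s <- g@pixelSize
  col <- floor((x - g@origin[1]) / s) + 1
  row <- floor((y - g@origin[2]) / s) + 1
  bad <- col < 1 | col > ncol(g@values) | row < 1 | row > nrow(g@values)
  if (any(bad))
    stop(sum(bad), " point(s) fall outside the grid extent")
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write a Grid as an Esri ASCII grid
#'
#' Plain-text single-band raster interchange. Values are written with full
#' double precision so `readAsciiGrid(writeAsciiGrid(g))` reproduces `g`
#' exactly. Because the package's y axis grows southward, `yllcorner`
#' holds the y of the corner furthest from the origin
#' (`y0 + nrows * cellsize`).
#'
#' @param g a \linkS4class{Grid}.
#' @param path output file path (conventionally `.asc`).
#' @param nodata the sentinel written for `NA` pixels.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(g, path, nodata = -9999) {
  v <- g@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", formatC(g@origin[1], format = "g", digits = 17)),
    paste("yllcorner",
          formatC(g@origin[2] + nrow(v) * g@pixelSize, format = "g",
                  digits = 17)),
    paste("cellsize", formatC(g@pixelSize, format = "g", digits = 17)),
    paste("NODATA_value", nodata)), con)
  out <- v
  out[is.na(out)] <- nodata
  writeLines(apply(out, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Read an Esri ASCII grid as a Grid
#'
#' @param path file path.
#' @return a \linkS4class{Grid}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  grid(m, pixelSize = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner - nr * hdr$cellsize))
}
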