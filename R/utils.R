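#' Canonical feature classes of the landscape
#'
#' The eight linear or areal feature classes that give rise to the
#' distance-to-feature predictors.
#'
#' @return character vector of class names.
#' @export
featureClasses <- function() {
  c("pools", "rivers", "residential", "national_road", "provincial_road",
    "expressway", "farmland_road", "ditch")
}

#' Canonical predictor names of the habitat stack
#'
#' The eleven predictor layers, in canonical order: eight
#' distance-to-feature layers, farmland patch area, and the NDVI mean and
#' maximum summaries.
#'
#' @return character vector of layer names.
#' @export
predictorNames <- function() {
  c(paste0("dist_", featureClasses()), "farmland_area", "mnndvi", "maxndvi")
}

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one explicit master seed.
#' Independent random streams (feature placement, NDVI noise, observation
#' simulation, background sampling, model fits, ...) use child seeds
#' derived deterministically by this linear-congruential mix, keeping every
#' derived seed a valid 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param stream small non-negative integer labelling the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + 12345 * stream) %%
               2147483647)
}

# 6-significant-digit float formatting shared by all report writers;
# fixed so regenerated reports are byte-identical.
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}
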