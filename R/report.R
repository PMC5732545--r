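#' Binned occurrence-abundance relation
#'
#' Extracts the RIO value at every presence point, bins into `nBins`
#' equal-width bins on `[0, 1]`, and reports the mean observed flock
#' count per bin — the occurrence-versus-abundance diagnostic. Empty bins
#' are kept with `n_points = 0` and `NA` mean.
#'
#' @param rio the RIO \linkS4class{Grid}.
#' @param observationSet an \linkS4class{ObservationSet}; only presence
#'   points are used.
#' @param nBins number of bins (default 10).
#' @return a \linkS4class{RelationCurve}.
#' @export
occurrenceAbundanceRelation <- function(rio, observationSet, nBins = 10L) {
  p <- observationSet@points
  p <- p[p$presence == 1, , drop = FALSE]
  if (!nrow(p)) stop("no presence points")
  cell <- pointToCell(rio, p$x, p$y)
  r <- rio@values[cbind(cell$row, cell$col)]
  keep <- !is.na(r)
  r <- r[keep]
  counts <- p$count[keep]
  bin <- pmin(floor(r * nBins) + 1L, nBins)
  centers <- (seq_len(nBins) - 0.5) / nBins
  n <- tabulate(bin, nbins = nBins)
  means <- rep(NA_real_, nBins)
  agg <- tapply(counts, factor(bin, levels = seq_len(nBins)), mean)
  means[!is.na(agg)] <- agg[!is.na(agg)]
  new("RelationCurve",
      curve = data.frame(rio_bin_center = centers,
                         mean_observed_count = means, n_points = n),
      scatter = data.frame(rio = r, count = counts))
}

setMethod("show", "RelationCurve", function(object) {
  cat(sprintf("RelationCurve: %d bins, %d presence points\n",
              nrow(object@curve), sum(object@curve$n_points)))
})

#' @describeIn occurrenceAbundanceRelation the binned curve data.frame.
#' @param x a RelationCurve.
#' @export
relationCurve <- function(x) x@curve

#' @describeIn occurrenceAbundanceRelation the raw (rio, count) scatter.
#' @export
relationScatter <- function(x) x@scatter

#' Land-cover composition summary
#'
#' Percentages of the study area covered by each land-cover component,
#' recomputed from the component areas.
#'
#' @param areas named numeric vector of component areas (km2).
#' @param total total study area (km2); defaults to including an "other"
#'   remainder when larger than `sum(areas)`.
#' @return data.frame with `class`, `area_km2`, `percent`.
#' @export
landCoverSummary <- function(areas, total = sum(areas)) {
  if (total <= 0) stop("total area must be positive")
  if (total < sum(areas) - 1e-9)
    stop("component areas exceed the total")
  data.frame(class = names(areas), area_km2 = as.numeric(areas),
             percent = 100 * as.numeric(areas) / total,
             row.names = NULL)
}

# fixed-format CSV writer: 6 significant digits, no quoting, so that
# regenerating a report from the same artifacts is byte-identical
writeReportCsv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- fmtNum(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predictor means at presence versus background points
#'
#' The habitat-comparison table: mean and standard deviation (n-1
#' denominator) of every predictor at presence points and at background
#' points.
#'
#' @param samples sample matrix with predictor columns and `presence`.
#' @return data.frame with `variable`, `presence_mean`, `presence_sd`,
#'   `background_mean`, `background_sd`.
#' @export
habitatComparison <- function(samples) {
  preds <- intersect(predictorNames(), names(samples))
  pres <- samples$presence == 1
  data.frame(
    variable = preds,
    presence_mean = vapply(preds, function(v) mean(samples[[v]][pres]), 0),
    presence_sd = vapply(preds, function(v) stats::sd(samples[[v]][pres]), 0),
    background_mean = vapply(preds, function(v) mean(samples[[v]][!pres]), 0),
    background_sd = vapply(preds, function(v) stats::sd(samples[[v]][!pres]), 0),
    row.names = NULL)
}

#' Write the diagnostics report
#'
#' Serializes the run's diagnostics to `outDir`: `metrics.json` (ROC,
#' RMSE, R2, adjustment A/B), `importance.csv`, `pd_curves.csv`,
#' `relation.csv`, `habitat_comparison.csv` and a human-readable
#' `summary.md`. All floats use 6 significant digits and no content
#' depends on time, so regeneration from the same artifacts is
#' byte-identical.
#'
#' @param metrics named list of scalar metrics (e.g. `roc_auc`, `rmse`,
#'   `r_squared`, `adjustment_A`, `adjustment_B`, `adjustment_r2`).
#' @param importance data.frame from [variableImportance()] (occurrence),
#'   optionally with an `model` column when stacking several models.
#' @param pdCurves data.frame of partial-dependence curves with columns
#'   `model`, `variable`, `value`, `response`.
#' @param relation a \linkS4class{RelationCurve}.
#' @param comparison data.frame from [habitatComparison()].
#' @param outDir output directory.
#' @return named character vector of files written, invisibly.
#' @export
renderReport <- function(metrics, importance, pdCurves, relation,
                         comparison, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  mp <- file.path(outDir, "metrics.json")
  jsonlite::write_json(lapply(metrics, function(x)
    if (is.numeric(x)) signif(x, 6) else x), mp,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["metrics"] <- mp

  paths["importance"] <- writeReportCsv(importance,
                                        file.path(outDir, "importance.csv"))
  paths["pd_curves"] <- writeReportCsv(pdCurves,
                                       file.path(outDir, "pd_curves.csv"))
  paths["relation"] <- writeReportCsv(relation@curve,
                                      file.path(outDir, "relation.csv"))
  paths["comparison"] <- writeReportCsv(
    comparison, file.path(outDir, "habitat_comparison.csv"))

  md <- c("# Occurrence + abundance model run", "",
          "## Metrics", "",
          paste0("- ", names(metrics), ": ",
                 vapply(metrics, function(x)
                   if (is.numeric(x)) fmtNum(x) else as.character(x), "")),
          "", "## Top occurrence predictors", "",
          paste0("- ", utils::head(importance$name, 5), " (",
                 fmtNum(utils::head(importance$score, 5)), ")"),
          "", "## Files", "",
          paste0("- ", basename(paths)))
  sp <- file.path(outDir, "summary.md")
  writeLines(md, sp)
  paths["summary"] <- sp
  invisible(paths)
}
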