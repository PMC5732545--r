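#' Run the full occurrence + abundance + priority pipeline
#'
#' End to end on a synthetic landscape: generate the landscape, build the
#' eleven-layer predictor stack, simulate flock observations, sample
#' pseudo-absences, fit the occurrence model and predict RIO, select
#' abundance predictors stepwise, fit the abundance model, calibrate it
#' linearly against observed counts (out-of-bag predictions), predict and
#' adjust the abundance surface, fuse RIO and adjusted RA into the
#' priority protection index, smooth the three surfaces for mapping, and
#' write surfaces, observations and the diagnostics report to `outDir`.
#'
#' @param landscapeCfg a \linkS4class{LandscapeConfig}.
#' @param responseCfg a \linkS4class{ResponseConfig}.
#' @param outDir output directory.
#' @param seed master seed for observation simulation, background
#'   sampling and model fits.
#' @param nBackground number of pseudo-absence points (default 10000,
#'   capped at the number of valid pixels).
#' @param nTrees trees per forest (default 1000).
#' @param trainFraction abundance train/test split fraction (default 0.8).
#' @param idw an \linkS4class{IdwParams} for the cosmetic smoothing.
#' @param smooth write IDW-smoothed companions of RIO / adjusted RA / PI
#'   (default TRUE). The PI math always uses unsmoothed pixel values.
#' @return invisibly, a list with the fitted objects, surfaces, metrics
#'   and file paths.
#' @export
runPipeline <- function(landscapeCfg, responseCfg, outDir, seed = 1L,
                        nBackground = 10000L, nTrees = 1000L,
                        trainFraction = 0.8, idw = idwParams(),
                        smooth = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  landscape <- generateLandscape(landscapeCfg)
  stack <- buildStack(landscape)
  obs <- simulateObservations(landscape, responseCfg, seed, stack = stack)

  nValid <- sum(landscape@studyMask@values == 1, na.rm = TRUE)
  bg <- samplePseudoAbsences(landscape@studyMask,
                             min(nBackground, nValid), seed)
  occSamples <- extractAtPoints(stack, combineObservations(obs, bg))
  occFit <- fitOccurrence(occSamples, nTrees = nTrees, seed = seed)
  rio <- predictRIO(occFit, stack)

  abundSamples <- extractAtPoints(stack, obs)
  split <- splitTrainTest(abundSamples, trainFraction, seed)
  selected <- stepwiseSelect(abundSamples, predictorNames(),
                             nTrees = max(200L, nTrees %/% 2L), seed = seed)
  if (!length(selected)) selected <- predictorNames()
  testFit <- fitAbundance(split$train, selected, nTrees = nTrees,
                          seed = seed)
  testPred <- predict(testFit@forest, split$test[selected])
  testR2 <- tryCatch(rSquared(split$test$count, testPred),
                     error = function(e) NA_real_)
  abundFit <- fitAbundance(abundSamples, selected, nTrees = nTrees,
                           seed = seed)
  adj <- fitAdjustment(abundSamples$count, abundFit@oobPredictions)
  raRaw <- predictAbundance(abundFit, stack)
  raAdj <- applyAdjustment(adj, raRaw)
  pi <- computePI(rio, raAdj)
  bundle <- surfaceBundle(rio, raRaw, raAdj, pi)

  metrics <- list(
    n_presence = sum(occSamples$presence == 1),
    n_background = sum(occSamples$presence == 0),
    roc_auc = oobRoc(occFit),
    rmse = rmse(abundSamples$count, abundFit@oobPredictions),
    r_squared_oob = rSquared(abundSamples$count, abundFit@oobPredictions),
    r_squared_test = testR2,
    selected_predictors = paste(selected, collapse = ","),
    adjustment_A = adj@A, adjustment_B = adj@B,
    adjustment_r2 = adj@rSquared)

  paths <- exportBundle(bundle, outDir,
                        meta = list(seed = seed, n_trees = nTrees,
                                    idw_power = idw@power, idw_k = idw@k))
  if (smooth) {
    for (nm in c("rio", "ra_adjusted", "pi")) {
      g <- switch(nm, rio = rio, ra_adjusted = raAdj, pi = pi)
      sm <- idwSmoothGrid(g, idw)
      p <- file.path(outDir, paste0(nm, "_smooth.asc"))
      writeAsciiGrid(sm, p)
      paths[paste0(nm, "_smooth")] <- p
    }
  }
  paths["observations"] <- writeObservations(
    obs, file.path(outDir, "observations.csv"))

  pd <- do.call(rbind, c(
    lapply(utils::head(variableImportance(occFit)$name, 4), function(v)
      cbind(model = "occurrence", variable = v,
            partialDependence(occFit, occSamples, v, nGrid = 50L))),
    lapply(selected, function(v)
      cbind(model = "abundance", variable = v,
            partialDependence(abundFit, abundSamples, v, nGrid = 50L)))))
  relation <- occurrenceAbundanceRelation(rio, obs)
  imp <- rbind(cbind(model = "occurrence", variableImportance(occFit)),
               cbind(model = "abundance", variableImportance(abundFit)))
  reportPaths <- renderReport(metrics, imp, pd, relation,
                              habitatComparison(occSamples),
                              file.path(outDir, "report"))

  invisible(list(landscape = landscape, stack = stack, observations = obs,
                 occurrenceFit = occFit, abundanceFit = abundFit,
                 adjustment = adj, bundle = bundle, metrics = metrics,
                 selected = selected, relation = relation,
                 paths = c(paths, reportPaths)))
}
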