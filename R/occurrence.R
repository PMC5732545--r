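#' Sample pseudo-absence (background) points
#'
#' Draws exactly `n` distinct valid pixels uniformly at random and returns
#' their centers as presence-0, count-0 points. Presence pixels are not
#' excluded, mirroring plain random background sampling; at study scale
#' the collision probability is negligible.
#'
#' @param studyMask binary \linkS4class{Grid}; pixels with value 1 and not
#'   nodata are valid.
#' @param n number of points (<= number of valid pixels).
#' @param seed integer seed.
#' @return an \linkS4class{ObservationSet} with provenance
#'   "pseudo-absence".
#' @export
samplePseudoAbsences <- function(studyMask, n, seed) {
  v <- studyMask@values
  valid <- which(!is.na(v) & v == 1)
  if (!length(valid)) stop("study mask has no valid pixels")
  if (n > length(valid))
    stop("n exceeds the number of valid pixels (", length(valid), ")")
  set.seed(childSeed(seed, 60L))
  idx <- if (n == length(valid)) valid else sample(valid, n)
  rc <- arrayInd(idx, dim(v))
  s <- studyMask@pixelSize
  new("ObservationSet",
      points = data.frame(
        x = studyMask@origin[1] + (rc[, 2] - 0.5) * s,
        y = studyMask@origin[2] + (rc[, 1] - 0.5) * s,
        count = 0, presence = 0),
      provenance = "pseudo-absence")
}

#' Combine presence and background observation sets
#'
#' @param ... \linkS4class{ObservationSet}s.
#' @return a combined ObservationSet with provenance "mixed".
#' @export
combineObservations <- function(...) {
  sets <- list(...)
  new("ObservationSet",
      points = do.call(rbind, lapply(sets, function(s) s@points)),
      provenance = "mixed")
}

#' Fit the occurrence model
#'
#' A random-forest classifier of presence against background with
#' balanced class weights `w_c = N / (2 N_c)` (so the minority presence
#' class is up-weighted against the 10,000-strong background sample) and
#' `nTrees` classification trees. Out-of-bag presence vote fractions are
#' stored per training point for validation.
#'
#' @param samples sample matrix from [extractAtPoints()]: predictor
#'   columns plus a 0/1 `presence` column.
#' @param nTrees number of trees (default 1000).
#' @param balanced use balanced class weights (default TRUE).
#' @param seed integer seed.
#' @return an \linkS4class{OccurrenceFit}.
#' @export
fitOccurrence <- function(samples, nTrees = 1000L, balanced = TRUE,
                          seed = 1L) {
  preds <- intersect(predictorNames(), names(samples))
  if (length(preds) < 2L)
    stop("need at least 2 predictor columns")
  if (!nrow(samples)) stop("empty sample matrix")
  y <- factor(samples$presence, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2L)
    stop("both presence and background classes must be present")
  N <- length(y)
  tabc <- table(y)
  w <- if (balanced) as.numeric(N / (2 * tabc)) else c(1, 1)
  names(w) <- names(tabc)
  set.seed(childSeed(seed, 70L))
  rf <- randomForest::randomForest(
    x = samples[preds], y = y, ntree = nTrees, classwt = w,
    importance = FALSE, keep.forest = TRUE)
  oob <- rf$votes[, "1"]
  if (anyNA(oob) || any(!is.finite(oob)))
    stop("some training points have no out-of-bag trees; increase nTrees")
  new("OccurrenceFit", forest = rf, training = samples, predictors = preds,
      oobScores = as.numeric(oob), nTrees = as.integer(nTrees),
      classWeights = w, seed = as.integer(seed))
}

setMethod("show", "OccurrenceFit", function(object) {
  cat(sprintf("OccurrenceFit: %d trees, %d training points (%d presences)\n",
              object@nTrees, nrow(object@training),
              sum(object@training$presence == 1)))
  cat(sprintf("  OOB ROC: %.3f\n", oobRoc(object)))
})

#' @describeIn fitOccurrence out-of-bag presence scores per training point.
#' @param fit an OccurrenceFit.
#' @export
oobScores <- function(fit) fit@oobScores

#' @describeIn fitOccurrence OOB ROC AUC of the fit (internal validation).
#' @export
oobRoc <- function(fit) rocAuc(fit@training$presence, fit@oobScores)

#' Predict the relative index of occurrence (RIO) surface
#'
#' For every valid pixel, the fraction of trees voting for the presence
#' class — an index from 0 to 1. Nodata pixels propagate.
#'
#' @param fit an \linkS4class{OccurrenceFit}.
#' @param stack a \linkS4class{PredictorStack} containing every training
#'   predictor.
#' @return a \linkS4class{Grid} with values in `[0, 1]`.
#' @export
predictRIO <- function(fit, stack) {
  missing <- setdiff(fit@predictors, names(stack@layers))
  if (length(missing))
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  ref <- stack@layers[[1]]
  df <- as.data.frame(lapply(stack@layers[fit@predictors],
                             function(g) as.vector(g@values)))
  names(df) <- fit@predictors
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    votes <- predict(fit@forest, df[ok, , drop = FALSE], type = "vote",
                     norm.votes = TRUE)
    out[ok] <- votes[, "1"]
  }
  gridLike(ref, matrix(out, nrow(ref@values), ncol(ref@values)))
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(1, 0), c(0.9, 0.1))  # 1
#' @export
rocAuc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Variable importance ranking
#'
#' Mean decrease in node impurity (Gini for the occurrence classifier,
#' residual sum of squares for the abundance regressor), all predictors,
#' sorted descending. Deterministic given the fit's seed.
#'
#' @param fit an \linkS4class{OccurrenceFit} or \linkS4class{AbundanceFit}.
#' @return data.frame with columns `name` and `score`, descending.
#' @export
variableImportance <- function(fit) {
  imp <- randomForest::importance(fit@forest)
  sc <- imp[, ncol(imp)]
  ord <- order(-sc)
  data.frame(name = rownames(imp)[ord], score = as.numeric(sc[ord]),
             row.names = NULL)
}

#' Partial dependence of the model response on one variable
#'
#' The standard substitution average: at each grid value `v` spanning the
#' variable's observed range, the mean model prediction over all training
#' rows with that variable set to `v`. For an occurrence fit the response
#' is the presence vote fraction; for an abundance fit the predicted
#' count.
#'
#' @param fit an \linkS4class{OccurrenceFit} or \linkS4class{AbundanceFit}.
#' @param samples sample matrix to marginalize over (typically the
#'   training data).
#' @param variable predictor name.
#' @param nGrid number of grid values (default 100).
#' @return data.frame with columns `value` and `response`.
#' @export
partialDependence <- function(fit, samples, variable, nGrid = 100L) {
  if (!variable %in% names(samples))
    stop("unknown variable: ", variable)
  base <- samples[fit@predictors]
  rng <- range(samples[[variable]])
  gridv <- seq(rng[1], rng[2], length.out = nGrid)
  predFun <- if (is(fit, "OccurrenceFit")) {
    function(d) mean(predict(fit@forest, d, type = "vote",
                             norm.votes = TRUE)[, "1"])
  } else {
    function(d) mean(predict(fit@forest, d))
  }
  resp <- vapply(gridv, function(v) {
    d <- base
    d[[variable]] <- v
    predFun(d)
  }, 0)
  data.frame(value = gridv, response = resp)
}
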