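#' Split a sample matrix into training and test sets
#'
#' Disjoint and exhaustive random partition with
#' `round(trainFraction * n)` training rows; deterministic given `seed`.
#'
#' @param samples a sample matrix (data.frame).
#' @param trainFraction fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
splitTrainTest <- function(samples, trainFraction = 0.8, seed = 1L) {
  n <- nrow(samples)
  if (n < 5L) stop("need at least 5 rows to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- round(trainFraction * n)
  set.seed(childSeed(seed, 80L))
  idx <- sample.int(n, nTrain)
  list(train = samples[idx, , drop = FALSE],
       test = samples[-idx, , drop = FALSE])
}

# OOB R-squared (explained-variance form, 1 - SSE/SST) of a single
# regression refit. This form goes negative when OOB predictions are
# worse than the mean, so noise candidates cannot clear the improvement
# threshold; -Inf when degenerate.
oobR2 <- function(samples, preds, nTrees, seed) {
  set.seed(seed)
  rf <- randomForest::randomForest(x = samples[preds], y = samples$count,
                                   ntree = nTrees)
  sst <- sum((samples$count - mean(samples$count))^2)
  if (sst < 1e-12) return(-Inf)
  1 - sum((samples$count - rf$predicted)^2) / sst
}

#' Greedy forward stepwise predictor selection
#'
#' Starting from the empty set, repeatedly adds the candidate that most
#' improves the out-of-bag R-squared of a refit abundance forest; stops
#' when the best improvement falls below `tol` or candidates are
#' exhausted. Ties break by candidate order. Deterministic given `seed`.
#' The selection criterion uses the explained-variance form of R-squared
#' (1 - SSE/SST on out-of-bag predictions), which is negative for
#' candidates predicting worse than the mean, so a lone uninformative
#' candidate is rejected rather than kept.
#'
#' @param samples sample matrix with a `count` column.
#' @param candidates candidate predictor names.
#' @param nTrees trees per refit (default 500; selection is a screening
#'   step, the final model is refit with its own `nTrees`).
#' @param seed integer seed.
#' @param tol minimum OOB R-squared improvement to keep adding
#'   (default 1e-3).
#' @return character vector of selected names (possibly empty).
#' @export
stepwiseSelect <- function(samples, candidates, nTrees = 500L, seed = 1L,
                           tol = 1e-3) {
  if (!length(candidates)) stop("no candidate predictors")
  selected <- character(0)
  current <- 0
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    r2 <- vapply(seq_along(remaining), function(i)
      oobR2(samples, c(selected, remaining[i]), nTrees,
            childSeed(seed, 90L + 100L * step + i)), 0)
    best <- which.max(r2)  # first max wins: candidate-order tie-break
    if (!is.finite(r2[best]) || r2[best] - current < tol) break
    selected <- c(selected, remaining[best])
    current <- r2[best]
  }
  selected
}

#' Fit the abundance model
#'
#' A random-forest regressor of flock counts on the selected predictors,
#' with out-of-bag predictions stored per training point.
#'
#' @param samples sample matrix with a `count` column (counts >= 0).
#' @param selected non-empty vector of predictor names.
#' @param nTrees number of regression trees (default 1000).
#' @param seed integer seed.
#' @return an \linkS4class{AbundanceFit}.
#' @export
fitAbundance <- function(samples, selected, nTrees = 1000L, seed = 1L) {
  if (!length(selected)) stop("empty predictor selection")
  if (!all(selected %in% names(samples)))
    stop("selected predictors missing from samples")
  if (stats::sd(samples$count) < 1e-12)
    stop("counts are constant; nothing to model")
  set.seed(childSeed(seed, 71L))
  rf <- randomForest::randomForest(x = samples[selected],
                                   y = samples$count, ntree = nTrees)
  new("AbundanceFit", forest = rf, training = samples,
      predictors = selected, oobPredictions = as.numeric(rf$predicted),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

setMethod("show", "AbundanceFit", function(object) {
  cat(sprintf("AbundanceFit: %d trees on %s\n", object@nTrees,
              paste(object@predictors, collapse = ", ")))
  cat(sprintf("  OOB RMSE: %.2f, OOB R2: %.3f\n",
              rmse(object@training$count, object@oobPredictions),
              rSquared(object@training$count, object@oobPredictions)))
})

#' @describeIn fitAbundance out-of-bag predicted counts.
#' @param fit an AbundanceFit.
#' @export
oobPredictions <- function(fit) fit@oobPredictions

#' Root mean squared error
#'
#' @param obs,pred equal-length numeric vectors.
#' @return `sqrt(mean((obs - pred)^2))`, in count units.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred) || !length(obs))
    stop("obs and pred must have equal nonzero length")
  sqrt(mean((obs - pred)^2))
}

#' R-squared between observed and predicted
#'
#' Default is the squared Pearson correlation (the usual
#' observed-vs-predicted scatter-plot R2); `method = "ss"` gives the
#' 1 - SSE/SST variant instead.
#'
#' @param obs,pred equal-length numeric vectors (n >= 3).
#' @param method "pearson" (default) or "ss".
#' @return R-squared (for "pearson", in `[0, 1]`).
#' @export
rSquared <- function(obs, pred, method = c("pearson", "ss")) {
  method <- match.arg(method)
  if (length(obs) != length(pred)) stop("length mismatch")
  if (length(obs) < 3L) stop("need at least 3 pairs")
  if (stats::sd(obs) < 1e-12 || (method == "pearson" && stats::sd(pred) < 1e-12))
    stop("zero variance")
  if (method == "pearson") stats::cor(obs, pred)^2
  else 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Fit the linear abundance adjustment
#'
#' Ordinary least squares of observed counts on predicted counts:
#' `observed = A * predicted + B`. Once A and B are known they calibrate
#' the whole predicted-abundance surface via [applyAdjustment()].
#'
#' @param obs observed counts (>= 3 values).
#' @param pred predicted counts, nonzero variance.
#' @return an \linkS4class{AdjustmentFit}.
#' @examples
#' fitAdjustment(c(5, 7, 9), c(1, 2, 3))  # A = 2, B = 3, R2 = 1
#' @export
fitAdjustment <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) < 3L)
    stop("need >= 3 equal-length pairs")
  if (stats::sd(pred) < 1e-12) stop("predictions have zero variance")
  fit <- stats::lm(obs ~ pred)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(obs) < 1e-12) 1 else stats::cor(obs, pred)^2
  new("AdjustmentFit", A = unname(co[2]), B = unname(co[1]),
      rSquared = min(1, r2), n = length(obs))
}

setMethod("show", "AdjustmentFit", function(object) {
  cat(sprintf(
    "AdjustmentFit: adjusted = %.4g * predicted + %.4g (R2 = %.3f, n = %d)\n",
    object@A, object@B, object@rSquared, object@n))
})

#' @describeIn fitAdjustment the slope A.
#' @param fit an AdjustmentFit.
#' @export
adjustmentSlope <- function(fit) fit@A

#' @describeIn fitAdjustment the intercept B.
#' @export
adjustmentIntercept <- function(fit) fit@B

#' @describeIn fitAdjustment the fit's R-squared.
#' @export
adjustmentR2 <- function(fit) fit@rSquared

#' Apply the abundance adjustment to a predicted surface
#'
#' Pixel-wise `A * ra + B`, clipped below at 0 (counts cannot be
#' negative); nodata propagates.
#'
#' @param fit an \linkS4class{AdjustmentFit}.
#' @param ra predicted-abundance \linkS4class{Grid}.
#' @return the adjusted \linkS4class{Grid}.
#' @export
applyAdjustment <- function(fit, ra) {
  gridLike(ra, pmax(fit@A * ra@values + fit@B, 0))
}

#' Predict the raw abundance surface
#'
#' Per-pixel ensemble mean predicted count over the stack. The raw
#' learner output is returned unclipped; clipping happens only in
#' [applyAdjustment()].
#'
#' @param fit an \linkS4class{AbundanceFit}.
#' @param stack a \linkS4class{PredictorStack} containing the selected
#'   predictors.
#' @return a \linkS4class{Grid}.
#' @export
predictAbundance <- function(fit, stack) {
  missing <- setdiff(fit@predictors, names(stack@layers))
  if (length(missing))
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  ref <- stack@layers[[1]]
  df <- as.data.frame(lapply(stack@layers[fit@predictors],
                             function(g) as.vector(g@values)))
  names(df) <- fit@predictors
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) out[ok] <- predict(fit@forest, df[ok, , drop = FALSE])
  gridLike(ref, matrix(out, nrow(ref@values), ncol(ref@values)))
}
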