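# Shared synthetic configurations for the property and recovery tests.

# graded ("staircase") occurrence signal: three nested NDVI kernels give a
# five-level p surface a forest can learn across its whole range
stairResponse <- function(nSites = 400L) {
  responseConfig(
    occurrence = data.frame(predictor = rep("mnndvi", 3),
                            low = c(0.10, 0.14, 0.18), high = 1,
                            penalty = 0.3),
    abundance = data.frame(predictor = "dist_national_road", low = 300,
                           high = 1200, penalty = 0.1),
    lambdaMax = 40, dispersion = 8, nSites = nSites)
}

smallLandscape <- function(seed, rows = 60L, cols = 60L) {
  generateLandscape(landscapeConfig(rows = rows, cols = cols, seed = seed))
}

# sample matrix with a single linearly separable driver (dist_pools) and
# noise in every other predictor column
separableSamples <- function(n = 500L, seed = 1L) {
  set.seed(seed)
  presence <- rep(c(0, 1), length.out = n)
  df <- data.frame(id = seq_len(n))
  for (nm in predictorNames()) df[[nm]] <- stats::rnorm(n)
  df$dist_pools <- ifelse(presence == 1, stats::runif(n, 1, 2),
                          stats::runif(n, -2, -1))
  df$presence <- presence
  df$count <- ifelse(presence == 1, 1, 0)
  df
}

# abundance samples whose counts are a noiseless function of two
# candidate predictors among noise candidates
twoDriverAbundance <- function(n = 400L, seed = 1L, noiseSd = 0) {
  set.seed(seed)
  df <- data.frame(id = seq_len(n))
  for (nm in predictorNames()[1:8]) df[[nm]] <- stats::runif(n)
  df$count <- 20 * df$dist_pools + 10 * (df$dist_ditch > 0.5) +
    stats::rnorm(n, 0, noiseSd)
  df$presence <- 1
  df
}
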