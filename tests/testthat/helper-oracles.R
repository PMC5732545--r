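# Independent brute-force oracles; deliberately naive implementations,
# kept free of any code path they are used to check.

# distance to nearest feature pixel: exhaustive min over feature pixels
bruteDistance <- function(mask, pixelSize) {
  fr <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask)))
    for (c in seq_len(ncol(mask)))
      out[r, c] <- sqrt(min((fr[, 1] - r)^2 + (fr[, 2] - c)^2)) * pixelSize
  out
}

# 4-connected component areas by queue-based flood fill
brutePatchArea <- function(mask, pixelSize) {
  out <- matrix(0, nrow(mask), ncol(mask))
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (mask[r0, c0] != 1 || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    cells <- list()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells[[length(cells) + 1L]] <- cur
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] == 1 && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    area <- length(cells) * pixelSize^2 / 1e6
    for (cell in cells) out[cell[1], cell[2]] <- area
  }
  out
}

# exhaustive pairwise ROC AUC with ties counted one half
bruteRocAuc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# full-neighbourhood IDW (k = all points)
bruteIdw <- function(pts, power, target) {
  ctr <- pixelCenters(target)
  out <- matrix(NA_real_, nrow(gridValues(target)), ncol(gridValues(target)))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    d <- sqrt((pts$x - ctr$x[c])^2 + (pts$y - ctr$y[r])^2)
    if (any(d < 1e-9)) out[r, c] <- pts$value[which.min(d)]
    else {
      w <- d^(-power)
      out[r, c] <- sum(w * pts$value) / sum(w)
    }
  }
  out
}

# closed-form simple OLS
bruteOls <- function(obs, pred) {
  A <- stats::cov(obs, pred) / stats::var(pred)
  B <- mean(obs) - A * mean(pred)
  c(A = A, B = B)
}
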