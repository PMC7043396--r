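# Independent brute-force oracles and small fixture builders used across
# the suite. Deliberately naive implementations: they check the package's
# optimised code paths, never share them.

# Exhaustive nearest-BS Euclidean distance.
bruteDistance <- function(extentValues, pixelSize = 1) {
  idx <- which(extentValues == 1L, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(extentValues), ncol(extentValues))
  for (r in seq_len(nrow(extentValues)))
    for (c in seq_len(ncol(extentValues)))
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  out * pixelSize
}

# Per-pixel enumeration of the in-grid disc proportion.
bruteFocal <- function(extentValues, radius) {
  nr <- nrow(extentValues); nc <- ncol(extentValues)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    num <- 0L; den <- 0L
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 > radius^2) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      den <- den + 1L
      num <- num + extentValues[rr, cc]
    }
    out[r, c] <- num / den
  }
  out
}

# Independent largest-remainder apportionment (floors, then remainders in
# decreasing order, earlier position wins ties).
oracleLargestRemainder <- function(w, total) {
  raw <- w * total
  base <- floor(raw + 1e-9)
  left <- round(total - sum(base))
  if (left > 0) {
    rem <- raw - base
    ord <- order(-rem, seq_along(w))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# All compositions of total into k nonnegative parts (k small).
allCompositions <- function(total, k) {
  if (k == 1L) return(matrix(total, 1, 1))
  out <- list()
  for (first in 0:total) {
    rest <- allCompositions(total - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Threshold-by-threshold ROC/PRC enumeration (predict positive when
# score >= threshold, one threshold per distinct score).
bruteCurves <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  roc <- prc <- NULL
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    roc <- rbind(roc, data.frame(threshold = t, fpr = fp / nNeg,
                                 tpr = tp / nPos))
    prc <- rbind(prc, data.frame(threshold = t, recall = tp / nPos,
                                 precision = tp / (tp + fp)))
  }
  list(roc = roc, prc = prc)
}

# Per-pixel confusion enumeration over an eligible set.
bruteConfusion <- function(modelled, reference, eligibleIdx) {
  tp <- fp <- fn <- tn <- 0L
  for (i in eligibleIdx) {
    if (modelled[i] == 1 && reference[i] == 1) tp <- tp + 1L
    else if (modelled[i] == 1 && reference[i] == 0) fp <- fp + 1L
    else if (modelled[i] == 0 && reference[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Small landscape used by the module tests: quick to generate, three
# observed years (two periods).
smallScenario <- function(seed = 5L, ...) {
  bsgmScenario(nRows = 60L, nCols = 60L, nUnits = 4L,
               observedYears = c(2000L, 2003L, 2006L), seed = seed, ...)
}

# First modelled BS year per pixel from an annual extent series.
modelledTransitionYear <- function(extents) {
  yrs <- sort(as.integer(names(extents)))
  grid <- gridSpec(extents[[1]])
  out <- matrix(NA_real_, grid@nRows, grid@nCols)
  for (y in rev(yrs)) {
    v <- rasterValues(extents[[as.character(y)]])
    out[v == 1L] <- y
  }
  out
}
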