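#' Confusion counts restricted to observed-transition pixels
#'
#' Compares a modelled and a reference extent over the eligible
#' (observed-transition) pixels only. Including pixels known not to
#' transition would grossly inflate agreement, so TP/FP/FN/TN are counted
#' exclusively where `eligible == 1`.
#'
#' @param modelled,reference [BinaryExtent-class] objects for the same
#'   year.
#' @param eligible 0/1 matrix from [transitionMask()].
#' @param zones optional [UnitZones-class]; when supplied, counts are
#'   reported per unit in addition to the global row.
#' @return data.frame with columns `unit_id` (`NA` for the global row),
#'   `tp, fp, fn, tn, n`.
#' @export
confusionOnTransitions <- function(modelled, reference, eligible,
                                   zones = NULL) {
  checkGrid(gridSpec(modelled), gridSpec(reference), "reference extent")
  m <- rasterValues(modelled); r <- rasterValues(reference)
  if (!all(dim(eligible) == dim(m)))
    stop("grid mismatch: eligible mask")
  sel <- which(eligible == 1L)
  if (length(sel) == 0L) stop("eligible set is empty")
  count <- function(idx) {
    mi <- m[idx]; ri <- r[idx]
    data.frame(tp = sum(mi == 1L & ri == 1L),
               fp = sum(mi == 1L & ri == 0L),
               fn = sum(mi == 0L & ri == 1L),
               tn = sum(mi == 0L & ri == 0L))
  }
  g <- cbind(unit_id = NA_integer_, count(sel))
  out <- g
  if (!is.null(zones)) {
    ids <- unitIds(zones)
    rows <- lapply(unitIndex(zones), function(u) {
      idx <- sel[ids[sel] == u]
      if (!length(idx))
        return(data.frame(unit_id = u, tp = 0L, fp = 0L, fn = 0L,
                          tn = 0L))
      cbind(unit_id = u, count(idx))
    })
    out <- rbind(g, do.call(rbind, rows))
  }
  out$n <- out$tp + out$fp + out$fn + out$tn
  out
}

#' Agreement metrics from confusion counts
#'
#' Adds the classification-agreement metrics to a confusion table: recall
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)`, precision `TP/(TP+FP)`, F1 (the
#' harmonic mean of precision and recall), quantity disagreement
#' `|FN-FP|/N`, allocation disagreement `2*min(FP,FN)/N`, and the
#' proportion correct `(TP+TN)/N`. Quantity plus allocation disagreement
#' equals the total disagreement, one minus the proportion correct. Metrics
#' with a zero denominator are reported as `NA` rather than 0, so
#' prevalence artefacts at the unit level stay visible.
#'
#' @param counts data.frame with columns `tp, fp, fn, tn` (e.g. from
#'   [confusionOnTransitions()]).
#' @return The input with metric columns appended.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  counts$recall <- safe(tp, tp + fn)
  counts$specificity <- safe(tn, fp + tn)
  counts$precision <- safe(tp, tp + fp)
  counts$f1 <- ifelse(!is.na(counts$precision) & !is.na(counts$recall) &
                        (counts$precision + counts$recall) > 0,
                      2 * counts$precision * counts$recall /
                        (counts$precision + counts$recall), NA_real_)
  counts$quantity_disagreement <- safe(abs(fn - fp), n)
  counts$allocation_disagreement <- safe(2 * pmin(fp, fn), n)
  counts$proportion_correct <- safe(tp + tn, n)
  counts
}

#' ROC and precision-recall curves with prevalence-matched sampling
#'
#' Evaluates classifier scores against binary labels over every score
#' threshold. When more pixels are available than `sampleSize`, a
#' stratified sample preserving the true transition prevalence is drawn
#' (the caller is responsible for excluding classifier-training pixels).
#' Reference curves for a random classifier (ROC diagonal; PRC horizontal
#' at the prevalence) and a perfect classifier are implied by the returned
#' prevalence.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels 0/1 vector of true transition labels.
#' @param sampleSize validation sample size (uses all pixels when fewer are
#'   available).
#' @param seed optional RNG seed for the sampling.
#' @return list with `roc` (data.frame `threshold, fpr, tpr`), `prc`
#'   (data.frame `threshold, recall, precision`), `auc` (trapezoidal ROC
#'   area), `prevalence`, and `nSampled`.
#' @export
rocPrcCurves <- function(scores, labels, sampleSize = 100000L,
                         seed = NULL) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!is.null(seed)) set.seed(seed)
  nAvail <- length(scores)
  if (nAvail > sampleSize) {
    prev <- mean(labels)
    nPos <- max(1L, round(sampleSize * prev))
    nNeg <- sampleSize - nPos
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    idx <- c(sample(pos, min(nPos, length(pos))),
             sample(neg, min(nNeg, length(neg))))
    scores <- scores[idx]; labels <- labels[idx]
  } else if (nAvail < sampleSize) {
    bsgmLog("validate", sprintf(
      "requested %d validation pixels, only %d available; using all",
      sampleSize, nAvail))
  }
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes required for ROC/PRC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cumTp <- cumsum(y); cumFp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct score
  thr <- s[last]
  tp <- cumTp[last]; fp <- cumFp[last]
  roc <- data.frame(threshold = thr, fpr = fp / nNeg, tpr = tp / nPos)
  prc <- data.frame(threshold = thr, recall = tp / nPos,
                    precision = tp / (tp + fp))
  fullFpr <- c(0, roc$fpr); fullTpr <- c(0, roc$tpr)
  auc <- sum(diff(fullFpr) * (utils::head(fullTpr, -1) +
                                utils::tail(fullTpr, -1)) / 2)
  list(roc = roc, prc = prc, auc = auc,
       prevalence = nPos / (nPos + nNeg),
       nSampled = nPos + nNeg)
}

# Per-slot confusion counts for a uniform-year assignment, via the k x k
# (assigned, true) contingency table and its 2-D cumulative sums.
slotConfusion <- function(assigned, trueSlot, k) {
  n <- length(trueSlot)
  if (k == 1L)
    return(data.frame(slot = 1L, tp = n, fp = 0L, fn = 0L, tn = 0L))
  M <- matrix(tabulate((trueSlot - 1L) * k + assigned, nbins = k * k),
              nrow = k)                      # rows: assigned, cols: true
  cs <- apply(apply(M, 2L, cumsum), 1L, cumsum)  # cs[t, a] after transpose
  aCum <- cumsum(rowSums(M)); tCum <- cumsum(colSums(M))
  tp <- diag(cs)
  data.frame(slot = seq_len(k), tp = tp, fp = aCum - tp, fn = tCum - tp,
             tn = n - aCum - tCum + tp)
}

#' Bootstrapped naive timing model
#'
#' The comparison baseline: every observed transition pixel of a period is
#' assigned a uniformly random year within the period (pixel identity is
#' fixed; only timing is random). Each bootstrap replicate yields per-year
#' confusion counts against the true timing, from which the agreement
#' metrics are computed; means and empirical 2.5/97.5 percentiles over
#' replicates are returned.
#'
#' @param trueSlot integer vector of true transition years, coded as slots
#'   1..k within the period (slot j = j-th year after the period start).
#' @param k number of assignable years in the period.
#' @param reps number of bootstrap replicates.
#' @param seed optional RNG seed.
#' @return list with `summary` (data.frame `slot, metric, mean, lo, hi`)
#'   and `reps` (the number of replicates).
#' @export
naiveModel <- function(trueSlot, k, reps = 500L, seed = NULL) {
  stopifnot(k >= 1L, all(trueSlot >= 1L & trueSlot <= k))
  if (!is.null(seed)) set.seed(seed)
  n <- length(trueSlot)
  metricCols <- c("tp", "recall", "specificity", "precision", "f1",
                  "quantity_disagreement", "allocation_disagreement",
                  "proportion_correct")
  acc <- array(NA_real_, dim = c(reps, k, length(metricCols)),
               dimnames = list(NULL, NULL, metricCols))
  for (b in seq_len(reps)) {
    assigned <- sample.int(k, n, replace = TRUE)
    cc <- classificationMetrics(slotConfusion(assigned, trueSlot, k))
    for (mc in metricCols) acc[b, , mc] <- cc[[mc]]
  }
  rows <- list()
  for (j in seq_len(k)) for (mc in metricCols) {
    v <- acc[, j, mc]
    rows[[length(rows) + 1L]] <- data.frame(
      slot = j, metric = mc, mean = mean(v, na.rm = TRUE),
      lo = unname(stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE)),
      hi = unname(stats::quantile(v, 0.975, na.rm = TRUE, names = FALSE)))
  }
  list(summary = do.call(rbind, rows), reps = reps)
}

#' Annual agreement of modelled extents with a reference series
#'
#' For every interpolated (interior) year, computes the agreement metrics
#' between the modelled extent and the reference extent, restricted to the
#' enclosing period's observed-transition pixels.
#'
#' @param modelled named list (by year) of modelled [BinaryExtent-class].
#' @param reference named list (by year) of reference [BinaryExtent-class]
#'   (e.g. withheld truth).
#' @param extents named list (by year) of the observed snapshots defining
#'   the periods' eligibility.
#' @param zones a [UnitZones-class].
#' @param timeframe a [TimeFrame-class].
#' @param water optional 0/1 water matrix.
#' @param perUnit also compute per-unit rows.
#' @return data.frame of metrics with a `year` column; global rows have
#'   `unit_id = NA`.
#' @export
annualAgreement <- function(modelled, reference, extents, zones, timeframe,
                            water = NULL, perUnit = FALSE) {
  per <- periods(timeframe)
  rows <- list()
  for (pi in seq_len(nrow(per))) {
    ts <- per$t_start[pi]; te <- per$t_end[pi]
    eligible <- transitionMask(extents[[as.character(ts)]],
                               extents[[as.character(te)]], water)
    if (sum(eligible) == 0L) next
    for (t in unobservedYears(timeframe, ts)) {
      cc <- confusionOnTransitions(modelled[[as.character(t)]],
                                   reference[[as.character(t)]], eligible,
                                   zones = if (perUnit) zones else NULL)
      rows[[length(rows) + 1L]] <- cbind(year = t,
                                         classificationMetrics(cc))
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
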