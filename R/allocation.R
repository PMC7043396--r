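#' Eligible-transition mask for a period
#'
#' Pixels observed non-BS at the period start and BS at the period end are
#' the only pixels the interpolative model may convert during the period;
#' this caps the spatial uncertainty at that of the input snapshots.
#'
#' @param extentStart,extentEnd observed [BinaryExtent-class] snapshots at
#'   the period endpoints.
#' @param water optional 0/1 water matrix; water pixels are never eligible.
#' @return 0/1 integer matrix of eligible pixels.
#' @export
transitionMask <- function(extentStart, extentEnd, water = NULL) {
  checkGrid(gridSpec(extentStart), gridSpec(extentEnd), "period endpoint")
  m <- (rasterValues(extentStart) == 0L) & (rasterValues(extentEnd) == 1L)
  if (!is.null(water)) m <- m & !(!is.na(water) & water == 1)
  storage.mode(m) <- "integer"
  m
}

#' Balanced training sample for the transition classifier
#'
#' Non-BS-to-BS transition labels over the full study span form a heavily
#' imbalanced set, so a stratified under-sample is drawn: 80% of the
#' transition pixels (capped at 50,000) and an equal number of
#' non-transition pixels, both without replacement, restricted to
#' study-area pixels (unit > 0, not water, covariates complete).
#'
#' @param extentT0,extentT1 observed snapshots at the first and last
#'   observed years.
#' @param zones a [UnitZones-class].
#' @param stack a [CovariateStack-class].
#' @param water optional 0/1 water matrix.
#' @param fraction fraction of transition pixels to sample.
#' @param cap maximum number of transition pixels sampled.
#' @param seed optional RNG seed for reproducible sampling.
#' @return A list of class `bsgmTrainingSample` with elements `idx`
#'   (sampled pixel indices, positives then negatives), `label` (factor
#'   "1"/"0"), and `X` (data.frame of covariate rows).
#' @export
sampleTrainingSet <- function(extentT0, extentT1, zones, stack,
                              water = NULL, fraction = 0.8, cap = 50000L,
                              seed = NULL) {
  checkGrid(gridSpec(zones), gridSpec(stack), "covariate stack")
  if (!is.null(seed)) set.seed(seed)
  ids <- unitIds(zones)
  e0 <- rasterValues(extentT0); e1 <- rasterValues(extentT1)
  ok <- ids > 0L & e0 == 0L
  if (!is.null(water)) ok <- ok & !(!is.na(water) & water == 1)
  for (l in covariateLayers(stack)) ok <- ok & !is.na(l)
  pos <- which(ok & e1 == 1L)
  neg <- which(ok & e1 == 0L)
  if (length(pos) == 0L)
    stop("no observed transitions between the study endpoints; ",
         "interpolation is vacuous")
  nPos <- min(floor(fraction * length(pos)), cap)
  nPos <- max(1L, as.integer(nPos))
  if (length(neg) < nPos) {
    warning("fewer non-transition pixels than requested; using ",
            length(neg))
    nPos <- length(neg)
  }
  sPos <- sample(pos, nPos)
  sNeg <- sample(neg, nPos)
  idx <- c(sPos, sNeg)
  X <- as.data.frame(lapply(covariateLayers(stack), function(l) l[idx]))
  out <- list(idx = idx,
              label = factor(rep(c("1", "0"), each = nPos),
                             levels = c("0", "1")),
              X = X)
  class(out) <- "bsgmTrainingSample"
  out
}

#' Fit the random-forest transition classifier
#'
#' Probability forest over the balanced training sample; the class-vote
#' fraction is the posterior transition probability and per-covariate
#' importance is the mean decrease in Gini impurity. All covariates are
#' retained.
#'
#' @param sample a `bsgmTrainingSample` from [sampleTrainingSet()].
#' @param nTrees number of trees.
#' @param seed RNG seed passed to the forest.
#' @return A fitted `ranger` probability forest.
#' @export
fitTransitionClassifier <- function(sample, nTrees = 500L, seed = NULL) {
  stopifnot(inherits(sample, "bsgmTrainingSample"))
  if (nlevels(droplevels(sample$label)) < 2L)
    stop("training sample contains a single class")
  df <- cbind(transition = sample$label, sample$X)
  ranger::ranger(transition ~ ., data = df, num.trees = nTrees,
                 probability = TRUE, importance = "impurity",
                 seed = seed, num.threads = 1L)
}

#' Predict the transition-probability surface
#'
#' Applies the fitted classifier to every study-area pixel of the covariate
#' stack; pixels outside the study area (or with incomplete covariates) are
#' `NA`.
#'
#' @param classifier fitted forest from [fitTransitionClassifier()].
#' @param stack a [CovariateStack-class] with the training layer names.
#' @param zones optional [UnitZones-class] restricting prediction to unit
#'   pixels.
#' @param water optional 0/1 water matrix excluded from prediction.
#' @return A [ProbabilitySurface-class].
#' @export
predictProbability <- function(classifier, stack, zones = NULL,
                               water = NULL) {
  need <- classifier$forest$independent.variable.names
  missing <- setdiff(need, covariateNames(stack))
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  grid <- gridSpec(stack)
  ok <- matrix(TRUE, grid@nRows, grid@nCols)
  if (!is.null(zones)) ok <- ok & unitIds(zones) > 0L
  if (!is.null(water)) ok <- ok & !(!is.na(water) & water == 1)
  for (l in covariateLayers(stack)[need]) ok <- ok & !is.na(l)
  idx <- which(ok)
  X <- as.data.frame(lapply(covariateLayers(stack)[need],
                            function(l) l[idx]))
  pred <- stats::predict(classifier, data = X, num.threads = 1L)$predictions
  P <- matrix(NA_real_, grid@nRows, grid@nCols)
  P[idx] <- pred[, "1"]
  new("ProbabilitySurface", grid = grid, values = P,
      importance = classifier$variable.importance)
}

#' Unit-normalised lights-at-night weights for one lag
#'
#' Min-max rescales the annual LAN brightness difference within each unit:
#' the unit's lowest lag maps to 0 and its highest to 1, so a relatively
#' large brightness increase marks a relatively likely transition. A
#' degenerate unit (all lags equal) gets the neutral weight 1 everywhere,
#' leaving the classifier ranking untouched.
#'
#' @param lan a [LANSeries-class].
#' @param zones a [UnitZones-class].
#' @param tau the most recent year of the lag (uses `LAN[tau] -
#'   LAN[tau-1]`).
#' @return Numeric matrix of weights in [0, 1]; `NA` outside the study
#'   area.
#' @export
lanWeights <- function(lan, zones, tau) {
  checkGrid(gridSpec(zones), gridSpec(lan), "LAN series")
  lag <- lanLag(lan, tau)
  ids <- unitIds(zones)
  w <- matrix(NA_real_, nrow(lag), ncol(lag))
  sel <- ids > 0L & !is.na(lag)
  lo <- tapply(lag[sel], ids[sel], min)
  hi <- tapply(lag[sel], ids[sel], max)
  rng <- hi - lo
  loPx <- lo[as.character(ids[sel])]
  rngPx <- rng[as.character(ids[sel])]
  w[sel] <- ifelse(rngPx > 0, (lag[sel] - loPx) / rngPx, 1)
  w
}

#' Year-specific adjusted transition probabilities
#'
#' Elementwise product of the study-span transition probability and the
#' year's LAN weight: `P_adj = wLAN * P`.
#'
#' @param psurf a [ProbabilitySurface-class] (or plain matrix).
#' @param wlan weight matrix from [lanWeights()].
#' @return Numeric matrix in [0, 1].
#' @export
adjustProbabilities <- function(psurf, wlan) {
  P <- if (is(psurf, "ProbabilitySurface")) rasterValues(psurf) else psurf
  if (!all(dim(P) == dim(wlan)))
    stop("grid mismatch between probabilities and LAN weights")
  P * wlan
}

#' Convert the top-n candidate pixels of one unit
#'
#' Among the period's eligible pixels of unit `unit` that are still non-BS,
#' the `n` highest adjusted probabilities transition; exact ties are broken
#' by a uniform random draw (scan order never decides). Demand exceeding
#' the remaining candidates is capped (and reported via the `shortfall`
#' element); with a conservative demand table this cannot happen.
#'
#' @param current 0/1 matrix of the current BS extent.
#' @param eligible 0/1 matrix from [transitionMask()].
#' @param padj adjusted-probability matrix for the year.
#' @param n number of pixels to convert.
#' @param zones a [UnitZones-class].
#' @param unit the unit ID to allocate within.
#' @return list with `values` (updated 0/1 matrix), `chosen` (converted
#'   pixel indices), `shortfall` (demand minus conversions).
#' @export
allocateYear <- function(current, eligible, padj, n, zones, unit) {
  ids <- unitIds(zones)
  cand <- which(ids == unit & eligible == 1L & current == 0L)
  nAsk <- as.integer(n)
  nTake <- min(nAsk, length(cand))
  chosen <- integer(0)
  if (nTake > 0L) {
    p <- padj[cand]
    p[is.na(p)] <- -Inf
    ord <- order(-p, stats::runif(length(cand)))
    chosen <- cand[ord[seq_len(nTake)]]
    current[chosen] <- 1L
  }
  list(values = current, chosen = chosen,
       shortfall = max(0L, nAsk - nTake))
}

#' Interpolate annual BS extents for every period
#'
#' The spatial-allocation loop: for each period, start from the observed
#' snapshot at the period's first year and, for each following year of the
#' period, weight the transition-probability surface by that year's LAN lag
#' (the lag ending at the year), allocate each unit's demanded transitions
#' to the top-ranked eligible pixels, and use the union with the previous
#' extent as the next year's base. Conservation of the demand table
#' guarantees the final year of each period reproduces the observed
#' snapshot exactly; observed years are emitted as pass-through.
#'
#' @param extents named list (by year) of observed [BinaryExtent-class]
#'   snapshots.
#' @param zones a [UnitZones-class].
#' @param demand demand table from [buildDemandTable()].
#' @param psurf a [ProbabilitySurface-class].
#' @param lan a [LANSeries-class] covering the study years.
#' @param timeframe a [TimeFrame-class].
#' @param water optional 0/1 water matrix.
#' @param seed optional seed for the tie-breaking RNG.
#' @return Named list (by year) of [BinaryExtent-class], one per year from
#'   the first to the last observed year.
#' @export
runInterpolation <- function(extents, zones, demand, psurf, lan, timeframe,
                             water = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- periods(timeframe)
  units <- unitIndex(zones)
  grid <- gridSpec(zones)
  checkGrid(grid, gridSpec(psurf), "probability surface")
  out <- list()
  shortfalls <- 0L
  for (pi in seq_len(nrow(per))) {
    ts <- per$t_start[pi]; te <- per$t_end[pi]
    extStart <- extents[[as.character(ts)]]
    extEnd <- extents[[as.character(te)]]
    checkGrid(grid, gridSpec(extStart), paste("extent", ts))
    eligible <- transitionMask(extStart, extEnd, water)
    current <- rasterValues(extStart)
    out[[as.character(ts)]] <- extStart
    for (t in seq.int(ts + 1L, te)) {
      wlan <- lanWeights(lan, zones, t)
      padj <- adjustProbabilities(psurf, wlan)
      for (u in units) {
        drow <- demand[demand$unit_id == u & demand$year == t &
                         demand$period_start == ts, ]
        n <- if (nrow(drow)) drow$bscnt_final else 0L
        if (n > 0L) {
          res <- allocateYear(current, eligible, padj, n, zones, u)
          current <- res$values
          shortfalls <- shortfalls + res$shortfall
        }
      }
      if (t < te) {
        out[[as.character(t)]] <- BinaryExtent(current, t, grid)
      } else {
        out[[as.character(te)]] <- extEnd
        if (!identical(current, rasterValues(extEnd)))
          warning("period ", ts, "-", te, ": allocated extent at ", te,
                  " does not reproduce the observed snapshot ",
                  "(non-conservative demand or non-nested inputs)")
      }
    }
  }
  if (shortfalls > 0L)
    warning("allocation demand exceeded remaining candidates for ",
            shortfalls, " pixel(s); demand table is not conservative")
  bsgmLog("allocate", sprintf("%d periods, %d years, %d units",
                              nrow(per), length(out), length(units)))
  out[order(as.integer(names(out)))]
}
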