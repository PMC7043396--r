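#' Extract per-unit population series at the observed years
#'
#' For every observed year, sums the gridded population inside the BS extent
#' of each unit (`BSPOP`), counts the unit's BS pixels (`BSCNT`), and
#' derives the unit-average BS population density `BSD = BSPOP / BSCNT`
#' (0 when the unit has no BS pixels). Total population `K` comes from the
#' annual unit table.
#'
#' @param popRasters named list (by year) of gridded population matrices at
#'   the observed years.
#' @param extents named list (by year) of [BinaryExtent-class] snapshots at
#'   the observed years.
#' @param zones a [UnitZones-class].
#' @param popTable data.frame `unit_id, year, value` of annual total
#'   population K per unit (must cover every observed year).
#' @return data.frame with columns `unit_id, year, K, BSPOP, BSCNT, BSD`.
#' @export
extractUnitSeries <- function(popRasters, extents, zones, popTable) {
  stopifnot(is(zones, "UnitZones"))
  years <- as.integer(names(extents))
  units <- unitIndex(zones)
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    yr <- years[i]
    if (!as.character(yr) %in% names(popRasters))
      stop("no population raster for observed year ", yr)
    if (!any(popTable$year == yr))
      stop("year ", yr, " present in extents but absent from the population table")
    ext <- extents[[as.character(yr)]]
    checkGrid(gridSpec(zones), gridSpec(ext), paste("extent", yr))
    ev <- rasterValues(ext)
    bspop <- zonalSum(popRasters[[as.character(yr)]], zones, mask = ev)
    bscnt <- zonalSum(ev, zones)
    k <- popTable$value[match(paste(units, yr),
                              paste(popTable$unit_id, popTable$year))]
    if (any(is.na(k)))
      stop("population table is missing units for year ", yr)
    out[[i]] <- data.frame(unit_id = units, year = yr, K = as.numeric(k),
                           BSPOP = as.numeric(bspop),
                           BSCNT = as.numeric(bscnt),
                           BSD = ifelse(bscnt > 0, bspop / bscnt, 0))
  }
  do.call(rbind, out)
}

#' Fit the period logistic growth curve for the BS population
#'
#' The BS population is modelled as logistic growth toward a dynamic
#' carrying capacity, the unit's total population K(t):
#' \deqn{BSPOP(t) = K(t) \frac{e^{r t + C}}{1 + e^{r t + C}}}
#' with t the year offset from the period start. r and C are obtained by a
#' least-squares line through the logit-transformed observations
#' `ln(BSPOP / (K - BSPOP))`; with the two period endpoints this is the
#' exact interpolating line. BSPOP is clipped to `[eps*K, (1-eps)*K]` before
#' transforming, since the logit is undefined at 0 and K.
#'
#' @param years observed years within the period (typically its two
#'   endpoints).
#' @param bspop BS population at those years.
#' @param K total population at those years (all > 0).
#' @param eps clipping fraction for the logit transform.
#' @return list with components `r` (per-year growth rate), `C`
#'   (intercept), and `t0` (the period start year, the origin of t).
#' @export
fitPeriodLogistic <- function(years, bspop, K, eps = 1e-6) {
  stopifnot(length(years) >= 2, length(bspop) == length(years),
            length(K) == length(years))
  if (any(!is.finite(K)) || any(K <= 0))
    stop("total population K must be positive at every observed year")
  bp <- pmin(pmax(bspop, eps * K), (1 - eps) * K)
  z <- log(bp / (K - bp))
  t <- years - years[1]
  if (length(years) == 2L) {
    r <- (z[2] - z[1]) / (t[2] - t[1])
    C <- z[1]
  } else {
    fit <- stats::lm.fit(cbind(1, t), z)
    C <- fit$coefficients[1]
    r <- fit$coefficients[2]
  }
  list(r = unname(r), C = unname(C), t0 = years[1])
}

#' Evaluate the interpolated BS population
#'
#' @param fit result of [fitPeriodLogistic()].
#' @param K_t total population at the target year.
#' @param t year offset from the period start (`year - fit$t0`).
#' @return BS population estimate, always inside `(0, K_t)`.
#' @export
interpolateBSPop <- function(fit, K_t, t) {
  K_t * stats::plogis(fit$r * t + fit$C)
}

#' Natural cubic spline through the observed BS densities
#'
#' Interpolates the unit-average BS population density across the whole
#' study span with a natural cubic spline (zero second derivative at the
#' end knots), using the observed years as knots. The spline passes through
#' every knot exactly and reproduces linear knot data exactly.
#'
#' @param years observed (knot) years, distinct, length >= 2.
#' @param bsd BS densities at the knots.
#' @return A function of year returning the interpolated density.
#' @export
fitDensitySpline <- function(years, bsd) {
  if (anyDuplicated(years)) stop("duplicate knot years")
  stopifnot(length(years) >= 2, all(is.finite(bsd)))
  stats::splinefun(years, bsd, method = "natural")
}

#' Estimated annual non-BS-to-BS transitions within a period
#'
#' Converts the interpolated BS population and density into an annual BS
#' pixel count `BSCNT(t) = BSPOP(t) / BSD(t)` and first-differences it:
#' the estimated transitions for year t are
#' `max(0, BSCNT(t) - BSCNT(t-1))` (negative growth clamped to zero, since
#' transitions are nonnegative by definition). Covers every year of the
#' period from `t_start + 1` to `t_end`; the count at `t_start` reproduces
#' the observed count because both interpolants pass through the
#' observations.
#'
#' @param fit period logistic fit from [fitPeriodLogistic()].
#' @param densityFun density spline from [fitDensitySpline()].
#' @param Kfun function of year returning the unit's total population.
#' @param tStart,tEnd the period's observed endpoint years.
#' @return data.frame `year, bscnt_hat` with the estimated transitions per
#'   year, or `NULL` when the interpolated density is not strictly positive
#'   on the period (caller falls back to uniform weights).
#' @export
estimateAnnualTransitions <- function(fit, densityFun, Kfun, tStart, tEnd) {
  yrs <- seq.int(tStart, tEnd)
  bsd <- densityFun(yrs)
  if (any(!is.finite(bsd)) || any(bsd <= 0)) return(NULL)
  bspop <- vapply(yrs, function(y) interpolateBSPop(fit, Kfun(y), y - fit$t0),
                  numeric(1))
  cnt <- bspop / bsd
  data.frame(year = yrs[-1L], bscnt_hat = pmax(0, diff(cnt)))
}

#' Annual demand weights within a period
#'
#' Normalizes the estimated annual transitions so the weights of a unit and
#' period sum to one. A degenerate all-zero estimate falls back to uniform
#' weights.
#'
#' @param est nonnegative estimated transitions, one per year of the
#'   period.
#' @return Weights summing to 1.
#' @export
computeWeights <- function(est) {
  stopifnot(all(est >= 0))
  s <- sum(est)
  if (s > 0) est / s else rep(1 / length(est), length(est))
}

#' Integer redistribution of a period's observed transitions
#'
#' Multiplies the period's observed transition total by the annual weights
#' and rounds to whole pixels while conserving the total exactly, using the
#' largest-remainder rule (ties toward the earlier year). This guarantees
#' the modelled extents rejoin the observed snapshots at period ends.
#'
#' @param w weights summing to 1.
#' @param deltaObs observed period transition total (nonnegative integer).
#' @return Integer allocations with `sum == deltaObs`.
#' @export
disaggregateTransitions <- function(w, deltaObs) {
  stopifnot(abs(sum(w) - 1) < 1e-8, deltaObs >= 0)
  largestRemainder(w, as.integer(deltaObs))
}

#' Build the full demand table
#'
#' Runs the demand-quantification chain for every unit and period: extract
#' observed series, fit the period logistic and the study-span density
#' spline, estimate annual transitions, normalize to weights, and
#' redistribute each period's observed transitions to its years. Units with
#' no BS at a period endpoint, or with a non-positive interpolated density,
#' fall back to uniform weights for that period.
#'
#' @param extents named list (by year) of observed [BinaryExtent-class]
#'   snapshots.
#' @param popRasters named list (by year) of gridded population matrices.
#' @param zones a [UnitZones-class].
#' @param popTable data.frame `unit_id, year, value` of annual total
#'   population (must cover every year of the study span).
#' @param timeframe a [TimeFrame-class].
#' @return data.frame with one row per (unit, period, year):
#'   `unit_id, period_start, period_end, year, bscnt_hat, w, bscnt_final,
#'   delta_obs`. Within each unit and period the `bscnt_final` column sums
#'   exactly to `delta_obs`.
#' @export
buildDemandTable <- function(extents, popRasters, zones, popTable,
                             timeframe) {
  stopifnot(is(timeframe, "TimeFrame"))
  series <- extractUnitSeries(popRasters, extents, zones, popTable)
  per <- periods(timeframe)
  units <- unitIndex(zones)
  ids <- unitIds(zones)
  rows <- list()
  for (u in units) {
    su <- series[series$unit_id == u, ]
    su <- su[order(su$year), ]
    densityFun <- fitDensitySpline(su$year, su$BSD)
    ku <- popTable[popTable$unit_id == u, ]
    Kfun <- function(y) {
      v <- ku$value[ku$year == y]
      if (!length(v)) stop("population table missing unit ", u, " year ", y)
      v
    }
    for (pi in seq_len(nrow(per))) {
      ts <- per$t_start[pi]; te <- per$t_end[pi]
      yrs <- seq.int(ts + 1L, te)
      e0 <- rasterValues(extents[[as.character(ts)]])
      e1 <- rasterValues(extents[[as.character(te)]])
      delta <- sum(ids == u & e0 == 0L & e1 == 1L)
      endpoints <- su[su$year %in% c(ts, te), ]
      est <- NULL
      if (all(endpoints$BSCNT > 0)) {
        fit <- fitPeriodLogistic(endpoints$year, endpoints$BSPOP,
                                 endpoints$K)
        est <- estimateAnnualTransitions(fit, densityFun, Kfun, ts, te)
      }
      if (is.null(est)) {
        est <- data.frame(year = yrs, bscnt_hat = NA_real_)
        w <- rep(1 / length(yrs), length(yrs))
      } else {
        w <- computeWeights(est$bscnt_hat)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u, period_start = ts, period_end = te, year = yrs,
        bscnt_hat = est$bscnt_hat, w = w,
        bscnt_final = disaggregateTransitions(w, delta),
        delta_obs = delta)
    }
  }
  do.call(rbind, rows)
}
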