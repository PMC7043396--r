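#' @include AllClasses.R
NULL

#' Accessors for bsgm data classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the bsgm S4 classes.
#' @param ... unused.
#' @return The requested component (see the individual methods).
#' @name bsgm-accessors
NULL

#' @rdname bsgm-accessors
#' @export
setGeneric("gridSpec", function(x, ...) standardGeneric("gridSpec"))
#' @rdname bsgm-accessors
#' @export
setGeneric("rasterValues", function(x, ...) standardGeneric("rasterValues"))
#' @rdname bsgm-accessors
#' @export
setGeneric("extentYear", function(x, ...) standardGeneric("extentYear"))
#' @rdname bsgm-accessors
#' @export
setGeneric("unitIds", function(x, ...) standardGeneric("unitIds"))
#' @rdname bsgm-accessors
#' @export
setGeneric("unitIndex", function(x, ...) standardGeneric("unitIndex"))
#' @rdname bsgm-accessors
#' @export
setGeneric("observedYears", function(x, ...) standardGeneric("observedYears"))
#' @rdname bsgm-accessors
#' @export
setGeneric("periods", function(x, ...) standardGeneric("periods"))
#' @rdname bsgm-accessors
#' @export
setGeneric("unobservedYears", function(x, ...)
  standardGeneric("unobservedYears"))
#' @rdname bsgm-accessors
#' @export
setGeneric("covariateNames", function(x, ...)
  standardGeneric("covariateNames"))
#' @rdname bsgm-accessors
#' @export
setGeneric("covariateLayers", function(x, ...)
  standardGeneric("covariateLayers"))
#' @rdname bsgm-accessors
#' @export
setGeneric("giniImportance", function(x, ...)
  standardGeneric("giniImportance"))
#' @rdname bsgm-accessors
#' @export
setGeneric("lanYears", function(x, ...) standardGeneric("lanYears"))

#' Annual lights-at-night lag raster
#'
#' Returns the brightness difference `LAN[tau] - LAN[tau - 1]`, where `tau`
#' is the most recent year of the lag.
#'
#' @param x a [LANSeries-class].
#' @param tau integer year; must have a predecessor in the series.
#' @return Numeric matrix of brightness differences.
#' @export
setGeneric("lanLag", function(x, tau) standardGeneric("lanLag"))

setMethod("gridSpec", "UnitZones", function(x, ...) x@grid)
setMethod("gridSpec", "BinaryExtent", function(x, ...) x@grid)
setMethod("gridSpec", "CovariateStack", function(x, ...) x@grid)
setMethod("gridSpec", "ProbabilitySurface", function(x, ...) x@grid)
setMethod("gridSpec", "LANSeries", function(x, ...) x@grid)

setMethod("rasterValues", "BinaryExtent", function(x, ...) x@values)
setMethod("rasterValues", "ProbabilitySurface", function(x, ...) x@values)

setMethod("extentYear", "BinaryExtent", function(x, ...) x@year)

setMethod("unitIds", "UnitZones", function(x, ...) x@ids)
setMethod("unitIndex", "UnitZones", function(x, ...) x@unitIndex)

setMethod("observedYears", "TimeFrame", function(x, ...) x@observedYears)

#' @describeIn bsgm-accessors periods as a data.frame with columns
#'   `t_start`, `t_end`.
setMethod("periods", "TimeFrame", function(x, ...) {
  y <- x@observedYears
  data.frame(t_start = y[-length(y)], t_end = y[-1L])
})

#' @describeIn bsgm-accessors integer years strictly inside the period
#'   starting at `t_start` (pass the period's start year as `t_start`).
#' @param t_start start year of the period of interest.
setMethod("unobservedYears", "TimeFrame", function(x, t_start, ...) {
  p <- periods(x)
  row <- p[p$t_start == t_start, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no period starts at year ", t_start)
  seq.int(row$t_start + 1L, row$t_end - 1L)
})

setMethod("covariateNames", "CovariateStack", function(x, ...)
  names(x@layers))
setMethod("covariateLayers", "CovariateStack", function(x, ...) x@layers)

setMethod("giniImportance", "ProbabilitySurface", function(x, ...)
  x@importance)

setMethod("lanYears", "LANSeries", function(x, ...) x@years)

setMethod("lanLag", "LANSeries", function(x, tau) {
  tau <- as.integer(tau)
  if (!(tau %in% x@years) || !((tau - 1L) %in% x@years))
    stop("lag requires rasters for both ", tau - 1L, " and ", tau)
  x@rasters[[as.character(tau)]] - x@rasters[[as.character(tau - 1L)]]
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d pixels, pixel size %g, origin (%g, %g), crs '%s'\n",
              object@nRows, object@nCols, object@pixelSize,
              object@origin[1], object@origin[2], object@crsTag))
})

setMethod("show", "UnitZones", function(object) {
  cat(sprintf("UnitZones: %d units over %d study pixels (%d x %d grid)\n",
              length(object@unitIndex), sum(object@ids > 0L),
              object@grid@nRows, object@grid@nCols))
})

setMethod("show", "BinaryExtent", function(object) {
  cat(sprintf("BinaryExtent %d: %d BS pixels on a %d x %d grid\n",
              object@year, sum(object@values),
              object@grid@nRows, object@grid@nCols))
})

setMethod("show", "TimeFrame", function(object) {
  p <- periods(object)
  cat(sprintf("TimeFrame: observed years {%s}, %d period(s)\n",
              paste(object@observedYears, collapse = ", "), nrow(p)))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack: %d layer(s) [%s] on a %d x %d grid\n",
              length(object@layers),
              paste(names(object@layers), collapse = ", "),
              object@grid@nRows, object@grid@nCols))
})

setMethod("show", "ProbabilitySurface", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("ProbabilitySurface: %d predicted pixels, mean P = %.3f\n",
              length(v), if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "LANSeries", function(object) {
  cat(sprintf("LANSeries: years %d-%d (%d lags) on a %d x %d grid\n",
              min(object@years), max(object@years),
              length(object@years) - 1L,
              object@grid@nRows, object@grid@nCols))
})
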