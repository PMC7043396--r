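#' @import methods
NULL

#' GridSpec: geometry shared by every raster in a model run
#'
#' Describes the common spatial grid all inputs and outputs of a run must
#' live on: dimensions, pixel size (abstract length units), lower-left
#' origin, and an opaque CRS tag. A "pixel" is the areal unit of every count
#' the model handles; rasters are stored as `nRows x nCols` matrices with
#' row 1 the top row.
#'
#' @slot nRows,nCols positive integers.
#' @slot pixelSize positive numeric, side length of a pixel.
#' @slot origin numeric(2), (x, y) of the lower-left corner.
#' @slot crsTag opaque character tag carried through I/O.
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer", pixelSize = "numeric",
                 origin = "numeric", crsTag = "character"),
  prototype(pixelSize = 1, origin = c(0, 0), crsTag = "local"))

setValidity("GridSpec", function(object) {
  msg <- NULL
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single positive integer")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be numeric(2)")
  if (length(object@crsTag) != 1L)
    msg <- c(msg, "crsTag must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param pixelSize pixel side length.
#' @param origin numeric(2), lower-left (x, y).
#' @param crsTag opaque CRS string.
#' @return A [GridSpec-class] object.
#' @examples
#' GridSpec(10, 10)
#' @export
GridSpec <- function(nRows, nCols, pixelSize = 1, origin = c(0, 0),
                     crsTag = "local") {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pixelSize = as.numeric(pixelSize), origin = as.numeric(origin),
      crsTag = as.character(crsTag))
}

#' UnitZones: subnational unit membership of every pixel
#'
#' Integer raster of unit IDs; ID 0 marks pixels outside the study area and
#' is never modelled. Units partition the nonzero pixels.
#'
#' @slot grid the shared [GridSpec-class].
#' @slot ids integer matrix of unit IDs (0 = outside study area).
#' @slot unitIndex sorted vector of the distinct positive unit IDs present.
#' @export
setClass("UnitZones",
  representation(grid = "GridSpec", ids = "matrix", unitIndex = "integer"))

setValidity("UnitZones", function(object) {
  msg <- NULL
  if (!all(dim(object@ids) == c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, "ids matrix does not match grid dimensions")
  present <- sort(unique(object@ids[object@ids > 0L]))
  if (!all(present %in% object@unitIndex))
    msg <- c(msg, "every nonzero pixel ID must appear in unitIndex")
  if (any(object@unitIndex <= 0L))
    msg <- c(msg, "unitIndex must contain positive IDs only")
  if (anyDuplicated(object@unitIndex))
    msg <- c(msg, "unitIndex must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct UnitZones from an ID raster
#'
#' @param ids integer matrix of unit IDs, 0 outside the study area.
#' @param grid the shared [GridSpec-class]; defaults to a unit grid matching
#'   `ids`.
#' @return A [UnitZones-class] object.
#' @export
UnitZones <- function(ids, grid = GridSpec(nrow(ids), ncol(ids))) {
  storage.mode(ids) <- "integer"
  new("UnitZones", grid = grid, ids = ids,
      unitIndex = sort(unique(ids[ids > 0L])))
}

#' BinaryExtent: a built-settlement snapshot
#'
#' A {0,1} raster marking built-settlement (BS) pixels at one year.
#'
#' @slot grid the shared [GridSpec-class].
#' @slot values {0,1} integer matrix.
#' @slot year integer year stamp.
#' @export
setClass("BinaryExtent",
  representation(grid = "GridSpec", values = "matrix", year = "integer"))

setValidity("BinaryExtent", function(object) {
  msg <- NULL
  if (!all(dim(object@values) == c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, "values matrix does not match grid dimensions")
  v <- object@values
  if (!all(v %in% c(0L, 1L)))
    msg <- c(msg, "values must be 0/1")
  if (length(object@year) != 1L || is.na(object@year))
    msg <- c(msg, "year must be a single integer")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BinaryExtent
#'
#' @param values 0/1 matrix.
#' @param year year stamp.
#' @param grid shared [GridSpec-class].
#' @return A [BinaryExtent-class] object.
#' @export
BinaryExtent <- function(values, year,
                         grid = GridSpec(nrow(values), ncol(values))) {
  storage.mode(values) <- "integer"
  new("BinaryExtent", grid = grid, values = values, year = as.integer(year))
}

#' TimeFrame: observed years and the periods between them
#'
#' Holds the ordered observed years T; consecutive pairs form the periods P
#' whose interior years the model interpolates.
#'
#' @slot observedYears strictly increasing integer vector, length >= 2.
#' @export
setClass("TimeFrame", representation(observedYears = "integer"))

setValidity("TimeFrame", function(object) {
  y <- object@observedYears
  if (length(y) < 2L) return("need at least two observed years")
  if (any(diff(y) <= 0L)) return("observed years must be strictly increasing")
  TRUE
})

#' Construct a TimeFrame
#'
#' @param observedYears integer vector of snapshot years, length >= 2.
#' @return A [TimeFrame-class] object.
#' @examples
#' tf <- TimeFrame(c(2000, 2005, 2010, 2015))
#' periods(tf)
#' @export
TimeFrame <- function(observedYears) {
  new("TimeFrame", observedYears = as.integer(sort(observedYears)))
}

#' CovariateStack: named predictor rasters on a shared grid
#'
#' @slot grid shared [GridSpec-class].
#' @slot layers named list of numeric matrices (unique names, none wholly
#'   NA).
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list"))

setValidity("CovariateStack", function(object) {
  msg <- NULL
  nm <- names(object@layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    msg <- c(msg, "layers must have unique non-empty names")
  dims <- c(object@grid@nRows, object@grid@nCols)
  for (i in seq_along(object@layers)) {
    if (!all(dim(object@layers[[i]]) == dims)) {
      msg <- c(msg, sprintf("layer '%s' does not match grid dimensions", nm[i]))
      break
    }
    if (all(is.na(object@layers[[i]]))) {
      msg <- c(msg, sprintf("layer '%s' is wholly nodata", nm[i]))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CovariateStack
#'
#' @param layers named list of numeric matrices.
#' @param grid shared [GridSpec-class].
#' @return A [CovariateStack-class] object.
#' @export
CovariateStack <- function(layers,
                           grid = GridSpec(nrow(layers[[1]]),
                                           ncol(layers[[1]]))) {
  new("CovariateStack", grid = grid, layers = layers)
}

#' ProbabilitySurface: per-pixel transition probability
#'
#' Posterior probability, from the transition classifier, that a pixel
#' transitions from non-BS to BS over the full study span, together with the
#' per-covariate mean decrease in Gini impurity.
#'
#' @slot grid shared [GridSpec-class].
#' @slot values numeric matrix in [0,1] (NA outside the study area).
#' @slot importance named numeric vector of Gini importances.
#' @export
setClass("ProbabilitySurface",
  representation(grid = "GridSpec", values = "matrix",
                 importance = "numeric"))

setValidity("ProbabilitySurface", function(object) {
  msg <- NULL
  if (!all(dim(object@values) == c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, "values matrix does not match grid dimensions")
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' LANSeries: annual lights-at-night brightness rasters
#'
#' One brightness raster per year; consecutive-year differences (lags) feed
#' the annual probability adjustment, so the number of usable lags is one
#' less than the number of years.
#'
#' @slot grid shared [GridSpec-class].
#' @slot years consecutive integer years.
#' @slot rasters list of numeric matrices, one per year, named by year.
#' @export
setClass("LANSeries",
  representation(grid = "GridSpec", years = "integer", rasters = "list"))

setValidity("LANSeries", function(object) {
  msg <- NULL
  if (length(object@years) < 2L)
    msg <- c(msg, "need at least two annual rasters to form a lag")
  if (any(diff(object@years) != 1L))
    msg <- c(msg, "years must be consecutive")
  if (length(object@rasters) != length(object@years))
    msg <- c(msg, "one raster per year required")
  if (!identical(names(object@rasters), as.character(object@years)))
    msg <- c(msg, "rasters must be named by year")
  dims <- c(object@grid@nRows, object@grid@nCols)
  for (r in object@rasters) if (!all(dim(r) == dims)) {
    msg <- c(msg, "raster dimensions must match the grid"); break
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a LANSeries
#'
#' @param rasters list of numeric matrices, one per consecutive year.
#' @param years integer vector of the years.
#' @param grid shared [GridSpec-class].
#' @return A [LANSeries-class] object.
#' @export
LANSeries <- function(rasters, years,
                      grid = GridSpec(nrow(rasters[[1]]), ncol(rasters[[1]]))) {
  names(rasters) <- as.character(years)
  new("LANSeries", grid = grid, years = as.integer(years), rasters = rasters)
}
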