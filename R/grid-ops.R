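#' Per-unit sums of a raster
#'
#' Sums `values` within each subnational unit, optionally restricted to
#' pixels where `mask == 1` (e.g. a BS extent, to extract BS population).
#' Nodata (`NA`) pixels never contribute; units with no selected pixels
#' return 0.
#'
#' @param values numeric matrix on the shared grid.
#' @param zones a [UnitZones-class].
#' @param mask optional 0/1 matrix selecting pixels.
#' @return Named numeric vector over `unitIndex(zones)`.
#' @examples
#' z <- UnitZones(matrix(rep(1:2, each = 8), 4, 4))
#' zonalSum(matrix(1, 4, 4), z)
#' @export
zonalSum <- function(values, zones, mask = NULL) {
  stopifnot(is(zones, "UnitZones"))
  if (!all(dim(values) == dim(unitIds(zones))))
    stop("grid mismatch: values do not match the zonal raster")
  ids <- unitIds(zones)
  sel <- !is.na(values) & ids > 0L
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(ids)))
      stop("grid mismatch: mask does not match the zonal raster")
    sel <- sel & !is.na(mask) & mask == 1
  }
  out <- stats::setNames(numeric(length(unitIndex(zones))),
                         unitIndex(zones))
  if (any(sel)) {
    s <- rowsum(values[sel], ids[sel])
    out[rownames(s)] <- s[, 1]
  }
  out
}

#' Zero an extent under a restrictive (water) mask
#'
#' Pixels covered by water can never hold built settlement: the extent is
#' forced to 0 there and left unchanged elsewhere. Idempotent.
#'
#' @param extent a [BinaryExtent-class].
#' @param water 0/1 matrix (1 = water).
#' @return A [BinaryExtent-class] with water pixels set to 0.
#' @export
applyRestrictiveMask <- function(extent, water) {
  stopifnot(is(extent, "BinaryExtent"))
  v <- rasterValues(extent)
  if (!all(dim(water) == dim(v)))
    stop("grid mismatch: water mask does not match the extent")
  v[!is.na(water) & water == 1] <- 0L
  BinaryExtent(v, extentYear(extent), gridSpec(extent))
}
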