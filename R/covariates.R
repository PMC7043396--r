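#' Euclidean distance to the nearest built-settlement pixel
#'
#' Exact Euclidean distance transform of the BS extent: 0 on BS pixels,
#' strictly positive elsewhere, in length units (`pixel distance *
#' pixelSize`).
#'
#' @param extent a [BinaryExtent-class] with at least one BS pixel.
#' @return Numeric matrix of distances.
#' @export
distanceToBSEdge <- function(extent) {
  stopifnot(is(extent, "BinaryExtent"))
  v <- rasterValues(extent)
  if (sum(v) == 0L)
    stop("extent has no BS pixels; distance to BS is undefined")
  d <- EBImage::distmap(1L - v, metric = "euclidean")
  as.matrix(d) * gridSpec(extent)@pixelSize
}

#' Proportion of built-settlement pixels in a circular neighbourhood
#'
#' For each pixel, the fraction of pixels within the disc of radius
#' `radiusPx` (centre included, centre distance <= radius) that are BS. At
#' grid borders the disc is truncated and the denominator is the in-grid
#' disc size, so values always lie in [0, 1].
#'
#' @param extent a [BinaryExtent-class].
#' @param radiusPx disc radius in pixels (>= 1).
#' @return Numeric matrix in [0, 1].
#' @export
focalBSProportion <- function(extent, radiusPx) {
  stopifnot(is(extent, "BinaryExtent"), radiusPx >= 1)
  off <- discOffsets(radiusPx)
  v <- rasterValues(extent)
  num <- discSum(v, off)
  den <- discSum(matrix(1, nrow(v), ncol(v)), off)
  num / den
}

#' Assemble the covariate stack for the transition classifier
#'
#' Derives the BS-based predictors from the start-of-study extent — distance
#' to the nearest BS edge plus focal BS proportions at pixel radii 1, 5, 10
#' and 15 — and appends any supplied static layers (elevation, slope,
#' accessibility surrogates, ...). Only start-of-study BS covariates enter
#' the stack; intermediate modelled extents never feed back into it.
#'
#' @param extentT0 the [BinaryExtent-class] at the first observed year.
#' @param extras named list of additional numeric matrices on the same
#'   grid.
#' @param radii focal radii in pixels.
#' @return A [CovariateStack-class]. BS-derived layers are named
#'   `bs_dst` and `bs_prp_<radius>`.
#' @export
buildStack <- function(extentT0, extras = list(),
                       radii = c(1L, 5L, 10L, 15L)) {
  stopifnot(is(extentT0, "BinaryExtent"))
  grid <- gridSpec(extentT0)
  layers <- list(bs_dst = distanceToBSEdge(extentT0))
  for (r in radii)
    layers[[sprintf("bs_prp_%d", r)]] <- focalBSProportion(extentT0, r)
  if (length(extras)) {
    if (is.null(names(extras)) || any(names(extras) == ""))
      stop("extra layers must be named")
    dup <- intersect(names(extras), names(layers))
    if (length(dup))
      stop("duplicate layer names: ", paste(dup, collapse = ", "))
    for (nm in names(extras)) {
      if (!all(dim(extras[[nm]]) == c(grid@nRows, grid@nCols)))
        stop("grid mismatch: extra layer '", nm, "'")
      layers[[nm]] <- extras[[nm]]
    }
  }
  CovariateStack(layers, grid)
}

#' Persist / load a covariate stack
#'
#' One `.asc` per layer plus a `manifest.csv` (`name,path`) in `dir`.
#'
#' @param stack a [CovariateStack-class].
#' @param dir output directory (created if needed).
#' @return `writeStack` the manifest path; `readStack` a
#'   [CovariateStack-class].
#' @export
writeStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- covariateNames(stack)
  paths <- file.path(dir, paste0(nm, ".asc"))
  for (i in seq_along(nm))
    writeRaster(covariateLayers(stack)[[i]], gridSpec(stack), paths[i])
  manifest <- data.frame(name = nm, path = basename(paths))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname writeStack
#' @export
readStack <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  grid <- NULL
  layers <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- readRaster(file.path(dir, manifest$path[i]), grid)
    if (is.null(grid)) grid <- r$grid
    layers[[manifest$name[i]]] <- r$values
  }
  CovariateStack(layers, grid)
}
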