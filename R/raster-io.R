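#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Rasters are exchanged as plain-text ESRI ASCII grids (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, top row first. A sidecar
#' `.prj` file, when present, supplies the CRS tag. Nodata cells are mapped
#' to `NA` and are excluded from every downstream count, sample, and metric.
#'
#' @param path path to an `.asc` file.
#' @param expectGrid optional [GridSpec-class]; if supplied, a mismatch with
#'   the file's geometry is a hard error (all rasters of a run must share
#'   one grid).
#' @return A list with elements `grid` (a [GridSpec-class]) and `values`
#'   (numeric matrix, `NA` = nodata).
#' @seealso [writeRaster()]
#' @export
readRaster <- function(path, expectGrid = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character(6)
  for (i in 1:6) hdr[i] <- readLines(con, n = 1L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "[[:space:]]+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in ", path)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(con, what = numeric(), n = nr * nc, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("raster body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  crsTag <- "local"
  prj <- sub("\\.asc$", ".prj", path)
  if (file.exists(prj)) crsTag <- readLines(prj, n = 1L)
  grid <- GridSpec(nr, nc, vals[["cellsize"]],
                   c(vals[["xllcorner"]], vals[["yllcorner"]]), crsTag)
  if (!is.null(expectGrid)) checkGrid(expectGrid, grid, basename(path))
  list(grid = grid, values = m)
}

#' Write a single-band raster as an ESRI ASCII grid file
#'
#' Inverse of [readRaster()]; round-trips values exactly (values are written
#' with full double precision). `NA` cells are written as the nodata value.
#'
#' @param values numeric matrix (row 1 = top row).
#' @param grid a [GridSpec-class] describing the geometry.
#' @param path output path (`.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid@nRows, ncol(values) == grid@nCols)
  if (any(values == nodata, na.rm = TRUE))
    stop("data contain the nodata sentinel ", nodata)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@origin[1]),
    sprintf("yllcorner %.10g", grid@origin[2]),
    sprintf("cellsize %.10g", grid@pixelSize),
    sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  if (!identical(grid@crsTag, "local"))
    writeLines(grid@crsTag, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' Read/write a BinaryExtent raster
#'
#' Thin wrappers over [readRaster()]/[writeRaster()] carrying the year
#' stamp.
#'
#' @param path file path.
#' @param year year stamp for the extent.
#' @param expectGrid optional [GridSpec-class] to enforce.
#' @return `readExtent` returns a [BinaryExtent-class]; `writeExtent`
#'   returns the path invisibly.
#' @export
readExtent <- function(path, year, expectGrid = NULL) {
  r <- readRaster(path, expectGrid)
  v <- r$values
  v[is.na(v)] <- 0
  BinaryExtent(v, year, r$grid)
}

#' @rdname readExtent
#' @param extent a [BinaryExtent-class].
#' @export
writeExtent <- function(extent, path) {
  writeRaster(rasterValues(extent), gridSpec(extent), path)
}

#' Read a unit x year table
#'
#' CSV with header `unit_id,year,value` is the interchange format for all
#' per-unit annual tables (e.g. total population K).
#'
#' @param path CSV path.
#' @return data.frame with integer `unit_id`, integer `year`, numeric
#'   `value`.
#' @export
readUnitTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "year", "value")
  if (!all(need %in% names(df)))
    stop("unit table must have columns unit_id, year, value")
  df$unit_id <- as.integer(df$unit_id)
  df$year <- as.integer(df$year)
  df$value <- as.numeric(df$value)
  df[need]
}

#' @rdname readUnitTable
#' @param df data.frame with columns `unit_id`, `year`, `value`.
#' @export
writeUnitTable <- function(df, path) {
  utils::write.csv(df[c("unit_id", "year", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
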