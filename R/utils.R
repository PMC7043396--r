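## Internal helpers shared across stages.

# Two GridSpecs are interchangeable when geometry agrees; crsTag is carried
# as metadata only but must not conflict.
sameGrid <- function(a, b) {
  isTRUE(a@nRows == b@nRows) && isTRUE(a@nCols == b@nCols) &&
    isTRUE(all.equal(a@pixelSize, b@pixelSize)) &&
    isTRUE(all.equal(a@origin, b@origin)) &&
    identical(a@crsTag, b@crsTag)
}

checkGrid <- function(a, b, what = "raster") {
  if (!sameGrid(a, b))
    stop("grid mismatch: ", what,
         " does not share the run's common GridSpec", call. = FALSE)
  invisible(TRUE)
}

# One global seed fans out to per-stage seeds by fixed offsets so each stage
# is independently reproducible. Kept well below .Machine$integer.max.
stageSeed <- function(seed, stage) {
  offsets <- c(synth = 1L, sample = 2L, forest = 3L, ties = 4L,
               curves = 5L, naive = 6L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

bsgmLog <- function(stage, ...) {
  message(sprintf("[bsgm:%s] %s | %s", stage,
                  format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
}

# Offsets (dr, dc) of the circular disc of radius r (centre included).
discOffsets <- function(radiusPx) {
  r <- as.integer(radiusPx)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Sum of m over the disc neighbourhood of each pixel, truncated at borders.
# Implemented as one shifted add per offset; grids here are small.
discSum <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] +
      m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

# Smooth mean-zero, unit-sd random field: white noise smoothed by repeated
# moving-average passes along rows and columns.
smoothField <- function(nRows, nCols, smoothPasses = 3L, window = 7L) {
  m <- matrix(stats::rnorm(nRows * nCols), nRows, nCols)
  k <- rep(1 / window, window)
  for (p in seq_len(smoothPasses)) {
    m <- apply(m, 2L, function(col)
      stats::filter(col, k, sides = 2, circular = TRUE))
    m <- t(apply(m, 1L, function(row)
      stats::filter(row, k, sides = 2, circular = TRUE)))
  }
  m <- m - mean(m)
  s <- stats::sd(m)
  if (s > 0) m <- m / s
  m
}

# Largest-remainder integer apportionment; ties broken toward the earlier
# position. Conserves sum(x) = total exactly.
largestRemainder <- function(w, total) {
  stopifnot(total >= 0, all(w >= 0))
  raw <- w * total
  base <- floor(raw + 1e-9)          # guard against 4.4999999 from fp noise
  rem <- raw - base
  need <- as.integer(round(total - sum(base)))
  if (need > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  } else if (need < 0) {
    ord <- order(rem, -seq_along(rem))
    take <- ord[base[ord] > 0][seq_len(-need)]
    base[take] <- base[take] - 1
  }
  as.integer(round(base))
}
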