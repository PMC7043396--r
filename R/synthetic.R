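#' Scenario configuration for the synthetic landscape generator
#'
#' Collects every tunable of the synthetic study landscape: grid size,
#' number of subnational units, observed snapshot years, per-unit growth
#' ranges, lights-at-night signal strength, and water fraction. Defaults
#' describe the package's reference scenario: a 120 x 120 grid, 9 units,
#' snapshots every five years over 2000-2015 (12 interior years across 3
#' periods), moderate settlement growth and an informative LAN signal.
#'
#' @param nRows,nCols grid dimensions.
#' @param nUnits number of contiguous subnational units.
#' @param observedYears snapshot years (length >= 2, increasing).
#' @param waterFraction fraction of pixels carved out as water.
#' @param capFraction per-unit settlement ceiling as a fraction of the
#'   unit's land pixels.
#' @param initShare,finalShare ranges (min, max) for the share of the
#'   ceiling occupied at the first and last observed year.
#' @param bsd0Range range of initial BS population density
#'   (persons/pixel).
#' @param bsdGrowthRange range of annual BS density growth rates.
#' @param ruralDensityRange range of non-BS land population density.
#' @param lanBase mean baseline LAN brightness.
#' @param lanJump brightness jump a pixel gains in its transition year.
#' @param lanNoiseSd standard deviation of iid annual LAN noise (0 gives a
#'   noiseless, fully informative signal).
#' @param nExtras number of smooth random static covariate layers.
#' @param pixelSize pixel side length for the [GridSpec-class].
#' @param seed scenario seed; all generated artefacts are reproducible
#'   from (seed, config).
#' @return list of class `bsgmScenario`.
#' @export
bsgmScenario <- function(nRows = 120L, nCols = 120L, nUnits = 9L,
                         observedYears = c(2000L, 2005L, 2010L, 2015L),
                         waterFraction = 0.05, capFraction = 0.25,
                         initShare = c(0.15, 0.25),
                         finalShare = c(0.60, 0.85),
                         bsd0Range = c(50, 150),
                         bsdGrowthRange = c(0, 0.02),
                         ruralDensityRange = c(2, 10),
                         lanBase = 10, lanJump = 30, lanNoiseSd = 5,
                         nExtras = 3L, pixelSize = 1, seed = 1L) {
  stopifnot(nUnits >= 1L, nUnits <= nRows * nCols,
            length(observedYears) >= 2L)
  out <- list(nRows = as.integer(nRows), nCols = as.integer(nCols),
              nUnits = as.integer(nUnits),
              observedYears = as.integer(sort(observedYears)),
              waterFraction = waterFraction, capFraction = capFraction,
              initShare = initShare, finalShare = finalShare,
              bsd0Range = bsd0Range, bsdGrowthRange = bsdGrowthRange,
              ruralDensityRange = ruralDensityRange,
              lanBase = lanBase, lanJump = lanJump,
              lanNoiseSd = lanNoiseSd, nExtras = as.integer(nExtras),
              pixelSize = pixelSize, seed = as.integer(seed))
  class(out) <- "bsgmScenario"
  out
}

#' Partition the grid into contiguous units and carve a water mask
#'
#' Units are the nearest-seed-point (Voronoi) partition of the grid, which
#' is contiguous by construction; water is the upper tail of a smooth
#' random field, carved at the configured fraction. Uses the current RNG
#' state ([generateLandscape()] seeds it from the scenario).
#'
#' @param scenario a `bsgmScenario`.
#' @return list with `zones` (a [UnitZones-class]) and `water` (0/1
#'   matrix).
#' @export
makeUnits <- function(scenario) {
  nr <- scenario$nRows; nc <- scenario$nCols
  grid <- GridSpec(nr, nc, scenario$pixelSize)
  seedPx <- sample.int(nr * nc, scenario$nUnits)
  sr <- (seedPx - 1L) %% nr + 1L
  sc <- (seedPx - 1L) %/% nr + 1L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  ids <- matrix(0L, nr, nc)
  for (u in seq_len(scenario$nUnits)) {
    d2 <- (rows - sr[u])^2 + (cols - sc[u])^2
    win <- d2 < best
    ids[win] <- u
    best[win] <- d2[win]
  }
  water <- matrix(0L, nr, nc)
  if (scenario$waterFraction > 0) {
    f <- smoothField(nr, nc)
    water[f > stats::quantile(f, 1 - scenario$waterFraction)] <- 1L
  }
  list(zones = UnitZones(ids, grid), water = water)
}

#' Grow the ground-truth settlement history
#'
#' Each unit follows a logistic pixel-count trajectory with known
#' parameters: the share of the unit's settlement ceiling grows from a
#' random initial to a random final share over the study span. Annual
#' counts are enforced exactly; only placement is random, with conversion
#' probability decaying with distance to the current settlement (mirroring
#' the proximity assumption the allocation model relies on). Every pixel's
#' transition year is recorded.
#'
#' @param zones a [UnitZones-class].
#' @param water 0/1 water matrix.
#' @param scenario a `bsgmScenario`.
#' @return list with `transYear` (matrix: `NA` never transitions, 0 = BS at
#'   the first year, else the transition year), `counts` (data.frame
#'   `unit_id, year, bscnt`), and `params` (per-unit data.frame of the true
#'   growth parameters `r`, `C`, `cap`, `bsd0`, `bsdGrowth`,
#'   `ruralDensity`, `nLand`).
#' @export
growTruth <- function(zones, water, scenario) {
  ids <- unitIds(zones)
  units <- unitIndex(zones)
  years <- seq.int(min(scenario$observedYears), max(scenario$observedYears))
  t0 <- years[1]; span <- length(years) - 1L
  nr <- nrow(ids); nc <- ncol(ids)
  transYear <- matrix(NA_real_, nr, nc)
  counts <- matrix(0L, length(units), length(years),
                   dimnames = list(units, years))
  params <- data.frame(unit_id = units, r = NA_real_, C = NA_real_,
                       cap = NA_real_, bsd0 = NA_real_,
                       bsdGrowth = NA_real_, ruralDensity = NA_real_,
                       nLand = NA_integer_)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_along(units)) {
    u <- units[k]
    land <- which(ids == u & water == 0L)
    params$nLand[k] <- length(land)
    params$bsd0[k] <- stats::runif(1, scenario$bsd0Range[1],
                                   scenario$bsd0Range[2])
    params$bsdGrowth[k] <- stats::runif(1, scenario$bsdGrowthRange[1],
                                        scenario$bsdGrowthRange[2])
    params$ruralDensity[k] <- stats::runif(1, scenario$ruralDensityRange[1],
                                           scenario$ruralDensityRange[2])
    if (length(land) < 8L) next     # too small to settle
    cap <- max(4, ceiling(scenario$capFraction * length(land)))
    p0 <- stats::runif(1, scenario$initShare[1], scenario$initShare[2])
    p1 <- stats::runif(1, scenario$finalShare[1], scenario$finalShare[2])
    C <- stats::qlogis(p0)
    r <- (stats::qlogis(p1) - C) / span
    cnt <- round(cap * stats::plogis(r * (years - t0) + C))
    cnt <- pmin(cummax(pmax(cnt, 1L)), length(land))
    counts[k, ] <- cnt
    params$r[k] <- r; params$C[k] <- C; params$cap[k] <- cap
    centre <- land[sample.int(length(land), 1L)]
    cr <- rows[centre]; cc <- cols[centre]
    d2c <- (rows[land] - cr)^2 + (cols[land] - cc)^2
    init <- land[order(d2c, stats::runif(length(land)))[seq_len(cnt[1])]]
    transYear[init] <- 0
  }
  bs <- !is.na(transYear)
  for (i in seq_along(years)[-1]) {
    t <- years[i]
    dist <- as.matrix(EBImage::distmap(1L - (bs * 1L),
                                       metric = "euclidean"))
    for (k in seq_along(units)) {
      need <- counts[k, i] - counts[k, i - 1L]
      if (need <= 0L) next
      cand <- which(ids == units[k] & water == 0L & !bs)
      wts <- exp(-dist[cand] / 2)
      pick <- cand[sample.int(length(cand), need, prob = wts)]
      transYear[pick] <- t
    }
    bs <- !is.na(transYear)
  }
  countsDf <- data.frame(unit_id = rep(units, times = length(years)),
                         year = rep(years, each = length(units)),
                         bscnt = as.vector(counts))
  list(transYear = transYear, counts = countsDf, params = params)
}

#' True BS extent at a given year
#'
#' @param truth result of [growTruth()] (or the `truth` element of a
#'   generated landscape).
#' @param year target year.
#' @param grid the shared [GridSpec-class].
#' @return A [BinaryExtent-class].
#' @export
truthExtent <- function(truth, year, grid) {
  v <- (!is.na(truth$transYear) & truth$transYear <= year) * 1L
  BinaryExtent(v, year, grid)
}

#' Generate a complete synthetic study landscape
#'
#' Produces, from a seeded scenario, everything a model run consumes —
#' unit zones, water mask, BS snapshots at the observed years only, annual
#' unit population table and gridded population at the observed years
#' (uniform at the unit BS density inside BS, uniform rural density
#' outside), annual LAN brightness with a configurable jump at each pixel's
#' transition year plus Gaussian noise, and smooth static covariate layers
#' — together with the withheld annual ground truth used only for
#' validation.
#'
#' Population is internally consistent: the unit total K(t) equals the sum
#' of the gridded population, and the BS population follows
#' `count(t) * BSD(t)` with `BSD(t) = bsd0 * (1 + g)^(t - t0)`.
#'
#' @param scenario a `bsgmScenario`.
#' @return list of class `bsgmLandscape` with elements `zones`, `water`,
#'   `snapshots` (named by observed year), `popRasters`, `popTable`, `lan`
#'   (a [LANSeries-class]), `extras`, `truth`, `timeframe`, `scenario`.
#' @export
generateLandscape <- function(scenario) {
  stopifnot(inherits(scenario, "bsgmScenario"))
  set.seed(stageSeed(scenario$seed, "synth"))
  uw <- makeUnits(scenario)
  zones <- uw$zones; water <- uw$water
  grid <- gridSpec(zones)
  truth <- growTruth(zones, water, scenario)
  years <- seq.int(min(scenario$observedYears), max(scenario$observedYears))
  t0 <- years[1]
  units <- unitIndex(zones)
  ids <- unitIds(zones)

  ## per-unit trajectories and the annual population table
  pr <- truth$params
  traj <- merge(truth$counts, pr, by = "unit_id")
  traj$BSD <- traj$bsd0 * (1 + traj$bsdGrowth)^(traj$year - t0)
  traj$BSPOP <- traj$bscnt * traj$BSD
  traj$K <- traj$BSPOP + traj$ruralDensity * (traj$nLand - traj$bscnt)
  popTable <- data.frame(unit_id = traj$unit_id, year = traj$year,
                         value = traj$K)

  ## gridded population at the observed years
  popRasters <- list()
  for (yr in scenario$observedYears) {
    ext <- truthExtent(truth, yr, grid)
    ev <- rasterValues(ext)
    m <- matrix(0, grid@nRows, grid@nCols)
    ty <- traj[traj$year == yr, ]
    for (k in seq_along(units)) {
      row <- ty[ty$unit_id == units[k], ]
      inU <- ids == units[k] & water == 0L
      m[inU & ev == 1L] <- row$BSD
      m[inU & ev == 0L] <- row$ruralDensity
    }
    popRasters[[as.character(yr)]] <- m
  }

  ## annual LAN brightness: static base field + jump at transition + noise
  baseField <- scenario$lanBase + 2 * smoothField(grid@nRows, grid@nCols)
  lanRasters <- lapply(years, function(t) {
    jumped <- (!is.na(truth$transYear) & truth$transYear <= t) * 1
    r <- baseField + scenario$lanJump * jumped
    if (scenario$lanNoiseSd > 0) {
      r <- r + matrix(stats::rnorm(grid@nRows * grid@nCols,
                                   sd = scenario$lanNoiseSd),
                      grid@nRows, grid@nCols)
    }
    r
  })
  lan <- LANSeries(lanRasters, years, grid)

  ## smooth static covariate extras
  extraNames <- c("elevation", "slope", "accessibility")
  extras <- list()
  if (scenario$nExtras > 0) {
    for (i in seq_len(scenario$nExtras)) {
      nm <- if (i <= length(extraNames)) extraNames[i] else
        sprintf("field%d", i)
      extras[[nm]] <- smoothField(grid@nRows, grid@nCols)
    }
  }

  snapshots <- lapply(scenario$observedYears, function(yr)
    applyRestrictiveMask(truthExtent(truth, yr, grid), water))
  names(snapshots) <- scenario$observedYears

  out <- list(zones = zones, water = water, snapshots = snapshots,
              popRasters = popRasters, popTable = popTable, lan = lan,
              extras = extras, truth = truth,
              timeframe = TimeFrame(scenario$observedYears),
              scenario = scenario)
  class(out) <- "bsgmLandscape"
  out
}

#' Write a generated landscape to disk
#'
#' Emits the model-facing inputs in the interchange formats (`.asc`
#' rasters, `unit_id,year,value` CSV) plus the withheld annual ground truth
#' under `withheld/` for validation only.
#'
#' @param landscape a `bsgmLandscape` from [generateLandscape()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
emitInputs <- function(landscape, dir) {
  stopifnot(inherits(landscape, "bsgmLandscape"))
  dir.create(file.path(dir, "withheld"), showWarnings = FALSE,
             recursive = TRUE)
  grid <- gridSpec(landscape$zones)
  paths <- list()
  p <- file.path(dir, "zones.asc")
  writeRaster(unitIds(landscape$zones), grid, p); paths$zones <- p
  p <- file.path(dir, "water.asc")
  writeRaster(landscape$water, grid, p); paths$water <- p
  for (yr in names(landscape$snapshots)) {
    p <- file.path(dir, sprintf("bs_extent_%s.asc", yr))
    writeExtent(landscape$snapshots[[yr]], p)
    paths[[sprintf("bs_extent_%s", yr)]] <- p
  }
  for (yr in names(landscape$popRasters)) {
    p <- file.path(dir, sprintf("pop_%s.asc", yr))
    writeRaster(landscape$popRasters[[yr]], grid, p)
    paths[[sprintf("pop_%s", yr)]] <- p
  }
  for (yr in as.character(lanYears(landscape$lan))) {
    p <- file.path(dir, sprintf("lan_%s.asc", yr))
    writeRaster(landscape$lan@rasters[[yr]], grid, p)
    paths[[sprintf("lan_%s", yr)]] <- p
  }
  for (nm in names(landscape$extras)) {
    p <- file.path(dir, sprintf("cov_%s.asc", nm))
    writeRaster(landscape$extras[[nm]], grid, p)
    paths[[sprintf("cov_%s", nm)]] <- p
  }
  p <- file.path(dir, "pop_table.csv")
  writeUnitTable(landscape$popTable, p); paths$pop_table <- p
  p <- file.path(dir, "withheld", "truth_transition_year.asc")
  writeRaster(landscape$truth$transYear, grid, p)
  paths$truth_transition_year <- p
  p <- file.path(dir, "withheld", "truth_counts.csv")
  utils::write.csv(landscape$truth$counts, p, row.names = FALSE)
  paths$truth_counts <- p
  bsgmLog("synth", sprintf("wrote %d artefacts to %s", length(paths), dir))
  invisible(paths)
}
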