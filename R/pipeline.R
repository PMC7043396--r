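#' Read a run configuration
#'
#' YAML configuration naming either a synthetic `scenario` or explicit
#' input paths, the global `seed`, and the model tunables. See the package
#' vignette for the schema.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

# Demand table taken directly from the withheld truth: per unit and year,
# the true number of transitions. Used to study allocation in isolation
# from demand error.
truthDemandTable <- function(truth, zones, timeframe) {
  ids <- unitIds(zones)
  ty <- truth$transYear
  per <- periods(timeframe)
  rows <- list()
  for (pi in seq_len(nrow(per))) {
    ts <- per$t_start[pi]; te <- per$t_end[pi]
    yrs <- seq.int(ts + 1L, te)
    for (u in unitIndex(zones)) {
      inU <- ids == u & !is.na(ty)
      final <- vapply(yrs, function(t) sum(inU & ty == t), integer(1))
      delta <- sum(final)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u, period_start = ts, period_end = te, year = yrs,
        bscnt_hat = as.numeric(final),
        w = if (delta > 0) final / delta else rep(1 / length(yrs),
                                                  length(yrs)),
        bscnt_final = final, delta_obs = delta)
    }
  }
  do.call(rbind, rows)
}

# Assemble an input bundle from configured file paths (the same shape
# generateLandscape() produces, minus truth unless a withheld raster is
# named).
readInputsBundle <- function(inputs) {
  zr <- readRaster(inputs$zones)
  grid <- zr$grid
  ids <- zr$values
  ids[is.na(ids)] <- 0
  zones <- UnitZones(matrix(as.integer(ids), nrow(ids), ncol(ids)), grid)
  water <- matrix(0L, grid@nRows, grid@nCols)
  if (!is.null(inputs$water)) {
    wr <- readRaster(inputs$water, grid)$values
    wr[is.na(wr)] <- 0
    water <- matrix(as.integer(wr), grid@nRows, grid@nCols)
  }
  years <- sort(as.integer(names(inputs$extents)))
  snapshots <- list()
  for (yr in years)
    snapshots[[as.character(yr)]] <- applyRestrictiveMask(
      readExtent(inputs$extents[[as.character(yr)]], yr, grid), water)
  popRasters <- lapply(inputs$pop_rasters, function(p)
    readRaster(p, grid)$values)
  names(popRasters) <- names(inputs$pop_rasters)
  lanYears <- sort(as.integer(names(inputs$lan)))
  lanRasters <- lapply(as.character(lanYears), function(yr)
    readRaster(inputs$lan[[yr]], grid)$values)
  extras <- list()
  for (nm in names(inputs$extras))
    extras[[nm]] <- readRaster(inputs$extras[[nm]], grid)$values
  truth <- NULL
  if (!is.null(inputs$truth_transition_year))
    truth <- list(transYear = readRaster(inputs$truth_transition_year,
                                         grid)$values)
  list(zones = zones, water = water, snapshots = snapshots,
       popRasters = popRasters,
       popTable = readUnitTable(inputs$pop_table),
       lan = LANSeries(lanRasters, lanYears, grid),
       extras = extras, truth = truth,
       timeframe = TimeFrame(years))
}

#' Run the full interpolation pipeline
#'
#' Orchestrates synthesis (or input loading), covariate derivation, demand
#' quantification, spatial allocation, and validation as one configured,
#' seeded run. When `outDir` is given, every stage writes its interchange
#' files (`.asc` rasters, CSV tables) and a `manifest.json`; with
#' `resume = TRUE`, stages whose outputs already exist are reloaded instead
#' of recomputed, reproducing identical results.
#'
#' @param config configuration list or path to a YAML file. Recognised
#'   keys: `seed`; `scenario` (arguments of [bsgmScenario()]) or `inputs`
#'   (paths: `zones`, `water`, `extents` (year -> path), `pop_rasters`,
#'   `pop_table`, `lan` (year -> path), `extras`,
#'   `truth_transition_year`); `model` (`n_trees`, `sample_fraction`,
#'   `sample_cap`, `demand_source` = `"model"` or `"truth"`); `validate`
#'   (logical); `naive_reps`.
#' @param outDir optional output directory for interchange files.
#' @param resume reload existing stage outputs instead of recomputing.
#' @param through last stage to execute: `"demand"`, `"allocate"`, or
#'   `"validate"`.
#' @return list with `inputs` (the landscape/input bundle), `demand`,
#'   `stack`, `sample`, `psurf`, `extents` (modelled annual
#'   [BinaryExtent-class] series), and when validated `metrics`, `naive`,
#'   `curves`; plus `manifest`.
#' @export
runBSGM <- function(config, outDir = NULL, resume = FALSE,
                    through = c("validate", "allocate", "demand")) {
  through <- match.arg(through)
  cfgPath <- NULL
  if (is.character(config)) {
    cfgPath <- config
    config <- readRunConfig(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  model <- config$model %||% list()
  nTrees <- as.integer(model$n_trees %||% 500L)
  sampleFraction <- model$sample_fraction %||% 0.8
  sampleCap <- as.integer(model$sample_cap %||% 50000L)
  demandSource <- model$demand_source %||% "model"
  naiveReps <- as.integer(config$naive_reps %||% 500L)
  doValidate <- isTRUE(config$validate %||% TRUE)
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## ---- stage: inputs (synthetic or from files) ----
  if (!is.null(config$scenario)) {
    scArgs <- config$scenario
    scArgs$seed <- scArgs$seed %||% seed
    if (!is.null(scArgs$observedYears))
      scArgs$observedYears <- as.integer(unlist(scArgs$observedYears))
    scenario <- do.call(bsgmScenario, scArgs)
    land <- generateLandscape(scenario)
    if (!is.null(outDir)) emitInputs(land, file.path(outDir, "inputs"))
  } else if (!is.null(config$inputs)) {
    land <- readInputsBundle(config$inputs)
  } else {
    stop("config must provide either 'scenario' or 'inputs'")
  }
  zones <- land$zones
  grid <- gridSpec(zones)
  tf <- land$timeframe
  obsYears <- observedYears(tf)
  bsgmLog("inputs", sprintf("%d x %d grid, %d units, observed years %s",
                            grid@nRows, grid@nCols,
                            length(unitIndex(zones)),
                            paste(obsYears, collapse = ",")))

  ## ---- stage: demand quantification ----
  demandPath <- if (!is.null(outDir)) file.path(outDir, "demand.csv")
  if (resume && !is.null(demandPath) && file.exists(demandPath)) {
    demand <- utils::read.csv(demandPath)
    bsgmLog("demand", "resumed from ", demandPath)
  } else {
    demand <- if (identical(demandSource, "truth")) {
      if (is.null(land$truth))
        stop("demand_source 'truth' requires a synthetic run or a ",
             "withheld truth raster")
      truthDemandTable(land$truth, zones, tf)
    } else {
      buildDemandTable(land$snapshots, land$popRasters, zones,
                       land$popTable, tf)
    }
    if (!is.null(demandPath))
      utils::write.csv(demand, demandPath, row.names = FALSE)
    bsgmLog("demand", sprintf("%d unit-period-years, %d transitions",
                              nrow(demand), sum(demand$bscnt_final)))
  }
  result <- list(inputs = land, demand = demand)
  if (through == "demand") return(finishRun(result, config, cfgPath,
                                            outDir, seed))

  ## ---- stage: covariates + probability surface ----
  t0 <- as.character(obsYears[1])
  t1 <- as.character(obsYears[length(obsYears)])
  stack <- buildStack(land$snapshots[[t0]], land$extras)
  trainSample <- sampleTrainingSet(land$snapshots[[t0]],
                                   land$snapshots[[t1]], zones, stack,
                                   water = land$water,
                                   fraction = sampleFraction,
                                   cap = sampleCap,
                                   seed = stageSeed(seed, "sample"))
  classifier <- fitTransitionClassifier(trainSample, nTrees = nTrees,
                                        seed = stageSeed(seed, "forest"))
  psurf <- predictProbability(classifier, stack, zones, land$water)
  bsgmLog("forest", sprintf("%d training pixels, %d trees, OOB error %.4f",
                            length(trainSample$idx), nTrees,
                            classifier$prediction.error))
  if (!is.null(outDir)) {
    writeRaster(rasterValues(psurf), grid,
                file.path(outDir, "p_transition.asc"))
    utils::write.csv(
      data.frame(name = names(giniImportance(psurf)),
                 importance = unname(giniImportance(psurf))),
      file.path(outDir, "importance.csv"), row.names = FALSE)
  }

  ## ---- stage: spatial allocation ----
  allYears <- seq.int(obsYears[1], obsYears[length(obsYears)])
  extentPaths <- if (!is.null(outDir))
    file.path(outDir, sprintf("bs_extent_%d.asc", allYears))
  if (resume && !is.null(outDir) && all(file.exists(extentPaths))) {
    extents <- lapply(seq_along(allYears), function(i)
      readExtent(extentPaths[i], allYears[i], grid))
    names(extents) <- allYears
    bsgmLog("allocate", "resumed modelled extents from ", outDir)
  } else {
    extents <- runInterpolation(land$snapshots, zones, demand, psurf,
                                land$lan, tf, water = land$water,
                                seed = stageSeed(seed, "ties"))
    if (!is.null(outDir))
      for (i in seq_along(allYears))
        writeExtent(extents[[as.character(allYears[i])]], extentPaths[i])
  }
  result$stack <- stack
  result$sample <- trainSample
  result$psurf <- psurf
  result$extents <- extents
  if (through == "allocate" || !doValidate || is.null(land$truth))
    return(finishRun(result, config, cfgPath, outDir, seed))

  ## ---- stage: validation against withheld truth ----
  truth <- land$truth
  reference <- lapply(allYears, function(yr)
    applyRestrictiveMask(truthExtent(truth, yr, grid), land$water))
  names(reference) <- allYears
  metrics <- annualAgreement(extents, reference, land$snapshots, zones,
                             tf, water = land$water, perUnit = TRUE)

  ## classifier curves on non-training pixels, prevalence preserved
  e0 <- rasterValues(land$snapshots[[t0]])
  e1 <- rasterValues(land$snapshots[[t1]])
  P <- rasterValues(psurf)
  cand <- which(!is.na(P) & e0 == 0L)
  cand <- setdiff(cand, trainSample$idx)
  curves <- rocPrcCurves(P[cand], e1[cand],
                         seed = stageSeed(seed, "curves"))

  ## bootstrapped naive timing baseline, per period
  per <- periods(tf)
  ids <- unitIds(zones)
  naiveRows <- list()
  set.seed(stageSeed(seed, "naive"))
  for (pi in seq_len(nrow(per))) {
    ts <- per$t_start[pi]; te <- per$t_end[pi]
    eligible <- transitionMask(land$snapshots[[as.character(ts)]],
                               land$snapshots[[as.character(te)]],
                               land$water)
    idx <- which(eligible == 1L)
    if (!length(idx)) next
    slots <- truth$transYear[idx] - ts
    k <- te - ts
    nv <- naiveModel(as.integer(slots), as.integer(k), reps = naiveReps)
    s <- nv$summary
    s$year <- ts + s$slot
    naiveRows[[pi]] <- s[s$year < te, c("year", "metric", "mean", "lo",
                                        "hi")]
  }
  naive <- do.call(rbind, naiveRows)
  if (!is.null(outDir)) {
    utils::write.csv(metrics, file.path(outDir, "metrics_by_year.csv"),
                     row.names = FALSE)
    utils::write.csv(naive, file.path(outDir, "naive_by_year.csv"),
                     row.names = FALSE)
    utils::write.csv(curves$roc, file.path(outDir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(curves$prc, file.path(outDir, "prc.csv"),
                     row.names = FALSE)
  }
  gm <- metrics[is.na(metrics$unit_id), ]
  bsgmLog("validate", sprintf(
    "mean proportion correct %.3f over %d interpolated years (AUC %.3f)",
    mean(gm$proportion_correct, na.rm = TRUE), nrow(gm), curves$auc))
  result$metrics <- metrics
  result$naive <- naive
  result$curves <- curves
  finishRun(result, config, cfgPath, outDir, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write the run manifest (config hash, seed, outputs); timestamps are kept
# out so identical configurations produce byte-identical manifests.
finishRun <- function(result, config, cfgPath, outDir, seed) {
  if (!is.null(outDir)) {
    hash <- if (!is.null(cfgPath)) unname(tools::md5sum(cfgPath)) else {
      tmp <- tempfile(fileext = ".yaml")
      yaml::write_yaml(config, tmp)
      h <- unname(tools::md5sum(tmp)); unlink(tmp); h
    }
    files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                          "manifest.json"))
    manifest <- list(config_hash = hash, seed = seed,
                     stages = names(result), files = files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
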