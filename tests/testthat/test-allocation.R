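test_that("the transition mask is confined to observed new settlement", {
  set.seed(12)
  e0 <- matrix(rbinom(100, 1, 0.3), 10, 10)
  e1 <- pmax(e0, matrix(rbinom(100, 1, 0.3), 10, 10))
  water <- matrix(rbinom(100, 1, 0.1), 10, 10)
  m <- transitionMask(BinaryExtent(e0, 2000), BinaryExtent(e1, 2005),
                      water)
  expect_true(all(m[e0 == 1L] == 0))      # never on existing BS
  expect_true(all(e1[m == 1L] == 1))      # subset of end-year BS
  expect_true(all(m[water == 1L] == 0))   # never on water
})

# A linearly separable fixture: one informative covariate, one pure noise.
separableFixture <- function(n = 30, prevalence = 0.4, seed = 99) {
  set.seed(seed)
  e0 <- matrix(0L, n, n)
  e0[1:3, ] <- 1L
  signal <- matrix(rnorm(n * n), n, n)
  e1 <- e0
  e1[e0 == 0L & signal > qnorm(1 - prevalence)] <- 1L
  ids <- matrix(1L, n, n)
  stack <- CovariateStack(list(signal = signal,
                               noise = matrix(rnorm(n * n), n, n)),
                          GridSpec(n, n))
  list(e0 = BinaryExtent(e0, 2000), e1 = BinaryExtent(e1, 2015),
       zones = UnitZones(ids), stack = stack)
}

test_that("training sampling is balanced, capped, and reproducible", {
  fx <- separableFixture()
  s <- sampleTrainingSet(fx$e0, fx$e1, fx$zones, fx$stack, seed = 1)
  nTrans <- sum(rasterValues(fx$e1) == 1L & rasterValues(fx$e0) == 0L)
  expect_equal(length(s$idx), 2 * floor(0.8 * nTrans))
  expect_equal(table(s$label)[["0"]], table(s$label)[["1"]])
  expect_false(any(duplicated(s$idx)))

  s2 <- sampleTrainingSet(fx$e0, fx$e1, fx$zones, fx$stack, seed = 1)
  expect_identical(s$idx, s2$idx)

  capped <- sampleTrainingSet(fx$e0, fx$e1, fx$zones, fx$stack,
                              cap = 50L, seed = 1)
  expect_equal(sum(capped$label == "1"), 50L)

  # ten transitions -> 8 positives + 8 negatives
  e0 <- matrix(0L, 10, 10)
  e1 <- e0; e1[1:10] <- 1L
  z <- UnitZones(matrix(1L, 10, 10))
  tiny <- CovariateStack(list(x = matrix(rnorm(100), 10, 10)),
                         GridSpec(10, 10))
  s3 <- sampleTrainingSet(BinaryExtent(e0, 2000), BinaryExtent(e1, 2015),
                          z, tiny, seed = 2)
  expect_equal(sum(s3$label == "1"), 8L)
  expect_equal(sum(s3$label == "0"), 8L)

  expect_error(sampleTrainingSet(BinaryExtent(e0, 2000),
                                 BinaryExtent(e0, 2015), z, tiny),
               "vacuous")
})

test_that("the classifier separates a separable fixture and ranks importance", {
  fx <- separableFixture()
  s <- sampleTrainingSet(fx$e0, fx$e1, fx$zones, fx$stack, seed = 1)
  rf <- fitTransitionClassifier(s, nTrees = 300, seed = 2)
  # out-of-bag accuracy from the vote fractions
  oobAcc <- function(model, labels) {
    p <- model$predictions[, "1"]
    mean((p > 0.5) == (labels == "1"), na.rm = TRUE)
  }
  expect_gt(oobAcc(rf, s$label), 0.95)

  imp <- rf$variable.importance
  expect_gt(imp[["signal"]], imp[["noise"]])

  # label permutation destroys the signal: accuracy near chance
  sNull <- s
  set.seed(5)
  sNull$label <- sample(sNull$label)
  rfNull <- fitTransitionClassifier(sNull, nTrees = 300, seed = 2)
  expect_lt(abs(oobAcc(rfNull, sNull$label) - 0.5), 0.1)

  oneClass <- s
  oneClass$label <- factor(rep("1", length(s$label)), levels = c("0", "1"))
  expect_error(fitTransitionClassifier(oneClass), "single class")
})

test_that("probability prediction is deterministic, bounded, and separating", {
  fx <- separableFixture()
  s <- sampleTrainingSet(fx$e0, fx$e1, fx$zones, fx$stack, seed = 1)
  rf <- fitTransitionClassifier(s, nTrees = 300, seed = 2)
  p1 <- predictProbability(rf, fx$stack, fx$zones)
  p2 <- predictProbability(rf, fx$stack, fx$zones)
  expect_identical(rasterValues(p1), rasterValues(p2))
  v <- rasterValues(p1)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))

  e0 <- rasterValues(fx$e0); e1 <- rasterValues(fx$e1)
  pos <- v[e0 == 0L & e1 == 1L]; neg <- v[e0 == 0L & e1 == 0L]
  expect_gt(mean(pos), mean(neg))

  broken <- CovariateStack(list(signal = rasterValues(p1) * 0),
                           gridSpec(fx$stack))
  expect_error(predictProbability(rf, broken), "missing layer")
})

test_that("LAN weights min-max rescale within units with a neutral fallback", {
  ids <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 2, 3)
  z <- UnitZones(ids)
  lanA <- matrix(0, 2, 3)
  lanB <- matrix(c(2, 4, 6, 5, 5, 5), 2, 3)  # unit 1: {2,4,6}; unit 2 flat
  lan <- LANSeries(list(lanA, lanB), c(2000, 2001), gridSpec(z))
  w <- lanWeights(lan, z, 2001)
  expect_equal(w[ids == 1L], c(0, 0.5, 1))
  expect_equal(w[ids == 2L], c(1, 1, 1))   # degenerate unit -> neutral 1

  set.seed(44)
  big <- UnitZones(matrix(sample(1:3, 64, replace = TRUE), 8, 8))
  lans <- LANSeries(list(matrix(rnorm(64), 8, 8),
                         matrix(rnorm(64), 8, 8)), c(2000, 2001),
                    gridSpec(big))
  wb <- lanWeights(lans, big, 2001)
  expect_true(all(wb >= 0 & wb <= 1, na.rm = TRUE))
})

test_that("probability adjustment is the elementwise product", {
  P <- matrix(0.8, 3, 3)
  expect_equal(adjustProbabilities(P, matrix(1, 3, 3)), P)
  expect_equal(adjustProbabilities(P, matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_equal(adjustProbabilities(P, matrix(0.5, 3, 3))[1, 1], 0.4)
})

test_that("top-n selection matches the full-sort oracle and is rank-based", {
  set.seed(77)
  ids <- matrix(1L, 12, 12)
  z <- UnitZones(ids)
  for (i in 1:10) {
    current <- matrix(rbinom(144, 1, 0.2), 12, 12)
    eligible <- matrix(0L, 12, 12)
    eligible[current == 0L] <- rbinom(sum(current == 0L), 1, 0.6)
    padj <- matrix(runif(144), 12, 12)
    n <- sample(0:sum(eligible & !current), 1)
    res <- allocateYear(current, eligible, padj, n, z, 1L)
    expect_equal(length(res$chosen), min(n, sum(eligible & !current)))
    # oracle: sorted top-n candidate probabilities (ties permute freely)
    cand <- which(ids == 1L & eligible == 1L & current == 0L)
    topVals <- sort(padj[cand], decreasing = TRUE)[seq_len(length(res$chosen))]
    expect_equal(sort(padj[res$chosen], decreasing = TRUE), topVals)
    # union with previous extent, nothing outside the mask
    expect_true(all(eligible[res$chosen] == 1L))
    expect_true(all(res$values[current == 1L] == 1L))
  }

  # exhaustion and no-demand edge cases
  current <- matrix(0L, 12, 12)
  eligible <- matrix(1L, 12, 12)
  padj <- matrix(runif(144), 12, 12)
  res <- allocateYear(current, eligible, padj, 144, z, 1L)
  expect_equal(sum(res$values), 144)
  res0 <- allocateYear(current, eligible, padj, 0, z, 1L)
  expect_identical(res0$values, current)

  # rank invariance: any positive rescaling selects the same pixels
  set.seed(10); a <- allocateYear(current, eligible, padj, 30, z, 1L)
  set.seed(10); b <- allocateYear(current, eligible, padj * 3.7, 30, z, 1L)
  expect_identical(sort(a$chosen), sort(b$chosen))
})

test_that("interpolation passes observed years through and nests extents", {
  land <- generateLandscape(smallScenario(seed = 6))
  demand <- buildDemandTable(land$snapshots, land$popRasters, land$zones,
                             land$popTable, land$timeframe)
  stack <- buildStack(land$snapshots[["2000"]], land$extras)
  s <- sampleTrainingSet(land$snapshots[["2000"]], land$snapshots[["2006"]],
                         land$zones, stack, water = land$water, seed = 3)
  rf <- fitTransitionClassifier(s, nTrees = 150, seed = 4)
  psurf <- predictProbability(rf, stack, land$zones, land$water)
  extents <- runInterpolation(land$snapshots, land$zones, demand, psurf,
                              land$lan, land$timeframe,
                              water = land$water, seed = 5)
  yrs <- sort(as.integer(names(extents)))
  expect_equal(yrs, 2000:2006)
  for (t in observedYears(land$timeframe))
    expect_identical(rasterValues(extents[[as.character(t)]]),
                     rasterValues(land$snapshots[[as.character(t)]]))
  for (i in seq_along(yrs)[-1]) {
    prev <- rasterValues(extents[[as.character(yrs[i - 1])]])
    curr <- rasterValues(extents[[as.character(yrs[i])]])
    expect_true(all(curr >= prev))
  }
})

test_that("zero demand leaves every annual extent at the period start", {
  land <- generateLandscape(smallScenario(seed = 6))
  demand <- buildDemandTable(land$snapshots, land$popRasters, land$zones,
                             land$popTable, land$timeframe)
  demand$bscnt_final <- 0L
  psurf <- new("ProbabilitySurface", grid = gridSpec(land$zones),
               values = matrix(0.5, 60, 60), importance = c(x = 1))
  w <- capture_warnings(
    extents <- runInterpolation(land$snapshots, land$zones, demand, psurf,
                                land$lan, land$timeframe,
                                water = land$water, seed = 5))
  expect_true(any(grepl("does not reproduce", w)))
  expect_identical(rasterValues(extents[["2002"]]),
                   rasterValues(land$snapshots[["2000"]]))
})
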