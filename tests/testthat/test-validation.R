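test_that("confusion counting is restricted to eligible pixels", {
  grid <- GridSpec(8, 8)
  set.seed(13)
  ref <- matrix(rbinom(64, 1, 0.4), 8, 8)
  eligible <- matrix(0L, 8, 8); eligible[1:40] <- 1L

  # perfect agreement: 15 BS among 40 eligible
  mod <- ref
  cc <- confusionOnTransitions(BinaryExtent(mod, 2003),
                               BinaryExtent(ref, 2003), eligible)
  expect_equal(cc$tp, sum(ref[1:40]))
  expect_equal(cc$tn, 40 - sum(ref[1:40]))
  expect_equal(cc$fp + cc$fn, 0L)

  # perfect disagreement
  cc <- confusionOnTransitions(BinaryExtent(1L - ref, 2003),
                               BinaryExtent(ref, 2003), eligible)
  expect_equal(cc$tp + cc$tn, 0L)

  # brute-force enumeration on a random pair over 30 eligible pixels
  mod <- matrix(rbinom(64, 1, 0.5), 8, 8)
  eligible30 <- matrix(0L, 8, 8); eligible30[sample(64, 30)] <- 1L
  cc <- confusionOnTransitions(BinaryExtent(mod, 2003),
                               BinaryExtent(ref, 2003), eligible30)
  oracle <- bruteConfusion(mod, ref, which(eligible30 == 1L))
  expect_equal(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn), oracle)

  expect_error(confusionOnTransitions(BinaryExtent(mod, 2003),
                                      BinaryExtent(ref, 2003),
                                      matrix(0L, 8, 8)), "empty")
})

test_that("agreement metrics reproduce the worked confusion table", {
  m <- classificationMetrics(data.frame(tp = 85, fp = 5, fn = 10,
                                        tn = 900))
  expect_equal(m$quantity_disagreement, 0.005)
  expect_equal(m$allocation_disagreement, 0.01)
  expect_equal(m$recall, 85 / 95)
  expect_equal(m$precision, 85 / 90)
  expect_equal(m$f1, 2 * (85 / 90) * (85 / 95) / ((85 / 90) + (85 / 95)))
  expect_equal(m$proportion_correct, 985 / 1000)

  perfect <- classificationMetrics(data.frame(tp = 10, fp = 0, fn = 0,
                                              tn = 30))
  expect_equal(perfect$quantity_disagreement, 0)
  expect_equal(perfect$allocation_disagreement, 0)
  expect_equal(perfect$f1, 1)

  pureAlloc <- classificationMetrics(data.frame(tp = 5, fp = 7, fn = 7,
                                                tn = 1))
  expect_equal(pureAlloc$quantity_disagreement, 0)
  expect_equal(pureAlloc$allocation_disagreement, 2 * 7 / 20)

  undef <- classificationMetrics(data.frame(tp = 0, fp = 0, fn = 0,
                                            tn = 12))
  expect_true(is.na(undef$recall))     # no reference positives
  expect_true(is.na(undef$precision))  # nothing predicted positive
})

test_that("disagreement identities hold over random confusion tables", {
  set.seed(23)
  for (i in 1:200) {
    cc <- data.frame(tp = rpois(1, 20), fp = rpois(1, 10),
                     fn = rpois(1, 10), tn = rpois(1, 50))
    if (sum(cc) == 0) next
    m <- classificationMetrics(cc)
    n <- sum(cc)
    expect_equal(m$quantity_disagreement + m$allocation_disagreement,
                 (cc$fp + cc$fn) / n, tolerance = 1e-12)
    expect_equal(1 - m$proportion_correct,
                 m$quantity_disagreement + m$allocation_disagreement,
                 tolerance = 1e-12)
  }
})

test_that("ROC/PRC match exhaustive threshold enumeration", {
  # 10-pixel hand example with tied scores
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.4, 0.4, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  got <- rocPrcCurves(scores, labels)
  oracle <- bruteCurves(scores, labels)
  expect_equal(got$roc$threshold, oracle$roc$threshold)
  expect_equal(got$roc$fpr, oracle$roc$fpr)
  expect_equal(got$roc$tpr, oracle$roc$tpr)
  expect_equal(got$prc$recall, oracle$prc$recall)
  expect_equal(got$prc$precision, oracle$prc$precision)

  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    got <- rocPrcCurves(scores, labels)
    oracle <- bruteCurves(scores, labels)
    expect_equal(got$roc$fpr, oracle$roc$fpr)
    expect_equal(got$roc$tpr, oracle$roc$tpr)
    expect_equal(got$prc$precision, oracle$prc$precision)
  }
})

test_that("ROC area behaves at the perfect and null extremes", {
  set.seed(41)
  labels <- rbinom(2000, 1, 0.3)
  perfect <- rocPrcCurves(labels + runif(2000) * 0.1, labels)
  expect_equal(perfect$auc, 1)
  expect_true(all(perfect$prc$precision[perfect$prc$recall < 1] == 1))

  null <- rocPrcCurves(runif(2000), labels)
  expect_lt(abs(null$auc - 0.5), 0.05)

  # agreement with an independent AUC implementation
  scores <- rnorm(500) + labels[1:500]
  got <- rocPrcCurves(scores, labels[1:500])
  ref <- as.numeric(pROC::auc(pROC::roc(labels[1:500], scores,
                                        quiet = TRUE)))
  expect_equal(got$auc, ref, tolerance = 1e-9)
})

test_that("prevalence-matched sampling preserves the transition rate", {
  set.seed(52)
  labels <- rbinom(50000, 1, 0.07)
  scores <- runif(50000)
  got <- rocPrcCurves(scores, labels, sampleSize = 10000, seed = 9)
  expect_equal(got$nSampled, 10000)
  expect_equal(got$prevalence, mean(labels), tolerance = 0.01)
})

test_that("the naive model is exact when the period has no freedom", {
  res <- naiveModel(rep(1L, 25), k = 1L, reps = 10)
  pc <- res$summary[res$summary$metric == "proportion_correct", ]
  expect_equal(pc$mean, 1)
})

test_that("naive per-year expectations match exact enumeration", {
  # 20 pixels, k = 5: E[TP at slot j] = sum over pixels with true slot <= j
  # of P(assigned <= j) = (#true <= j) * j / k under uniform assignment
  trueSlot <- rep(1:5, each = 4)
  k <- 5L
  reps <- 2000L
  res <- naiveModel(trueSlot, k, reps = reps, seed = 99)
  tpStats <- res$summary[res$summary$metric == "tp", ]
  for (j in 1:4) {
    nTrue <- sum(trueSlot <= j)
    expectation <- nTrue * j / k
    p <- j / k
    se <- sqrt(nTrue * p * (1 - p) / reps)
    expect_lt(abs(tpStats$mean[tpStats$slot == j] - expectation),
              3 * max(se, 1e-8))
  }
})

test_that("annual agreement restricts to each period's transitions", {
  land <- generateLandscape(smallScenario(seed = 8))
  grid <- gridSpec(land$zones)
  yrs <- 2000:2006
  reference <- lapply(yrs, function(y)
    applyRestrictiveMask(truthExtent(land$truth, y, grid), land$water))
  names(reference) <- yrs
  # a fake "model" that switches everything on immediately
  eager <- lapply(yrs, function(y) {
    v <- rasterValues(land$snapshots[["2006"]])
    BinaryExtent(v, y, grid)
  })
  names(eager) <- yrs
  m <- annualAgreement(eager, reference, land$snapshots, land$zones,
                       land$timeframe, water = land$water)
  expect_true(all(m$fn == 0))            # eager model never misses
  expect_true(all(m$recall == 1))
  # but over-predicts in early years of each period
  first <- m[m$year == 2001, ]
  expect_gt(first$fp, 0)
})
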