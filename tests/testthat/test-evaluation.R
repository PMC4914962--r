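test_that("average precision reproduces hand-enumerated rankings", {
  # one sample, q=3, true {l1, l2}, descending order (l1, l3, l2)
  expect_equal(averagePrecision(matrix(c(0.9, 0.2, 0.5), 1),
                                matrix(c(1, 1, 0), 1)),
               (1 / 1 + 2 / 3) / 2)
  # perfect ranking reaches the ceiling for every sample
  sc <- rbind(c(0.9, 0.8, 0.1), c(0.7, 0.2, 0.9))
  tr <- rbind(c(1, 1, 0), c(1, 0, 1))
  expect_equal(averagePrecision(sc, tr), 1)
  expect_error(averagePrecision(sc, tr[, 1:2]), "shape")
})

test_that("average precision equals an independent double-loop oracle", {
  set.seed(71)
  sc <- matrix(runif(200 * 6), 200)
  tr <- matrix(rbinom(200 * 6, 1, 0.35), 200)
  tr[rowSums(tr) == 0, 1] <- 1
  expect_equal(averagePrecision(sc, tr), oracleAP(sc, tr),
               tolerance = 1e-12)
  # with score ties (discretized scores), average tied ranks on both sides
  scTie <- round(sc * 4) / 4
  expect_equal(averagePrecision(scTie, tr), oracleAP(scTie, tr),
               tolerance = 1e-12)
})

test_that("AP is invariant under strictly increasing score transforms", {
  set.seed(72)
  sc <- matrix(runif(50 * 5), 50)
  tr <- matrix(rbinom(50 * 5, 1, 0.4), 50)
  tr[rowSums(tr) == 0, 2] <- 1
  base <- averagePrecision(sc, tr)
  expect_equal(averagePrecision(exp(3 * sc), tr), base, tolerance = 1e-12)
  expect_equal(averagePrecision(qlogis(sc / 2 + 0.25), tr), base,
               tolerance = 1e-12)
})

test_that("instances without true labels are excluded with a message", {
  sc <- rbind(c(0.9, 0.1), c(0.3, 0.4))
  tr <- rbind(c(1, 0), c(0, 0))
  expect_message(ap <- averagePrecision(sc, tr), "excluding 1")
  expect_equal(ap, 1)
})

test_that("bipartition metrics cover the exact, complement and mixed cases", {
  tr <- rbind(c(1, 0), c(0, 1))
  perfect <- suppressMessages(bipartitionMetrics(tr, tr))
  expect_equal(perfect$hammingLoss, 0)
  expect_equal(perfect$subsetAccuracy, 1)
  expect_equal(perfect$macroPrecision, 1)
  expect_equal(perfect$microF, 1)

  flipped <- suppressMessages(bipartitionMetrics(1 - tr, tr))
  expect_equal(flipped$hammingLoss, 1)

  oneWrong <- rbind(c(1, 0), c(1, 1))
  m <- suppressMessages(bipartitionMetrics(oneWrong, tr))
  expect_equal(m$hammingLoss, 0.25)
  expect_equal(m$subsetAccuracy, 0.5)

  # Hamming loss + cellwise accuracy = 1
  set.seed(73)
  p <- matrix(rbinom(60, 1, 0.5), 10)
  t2 <- matrix(rbinom(60, 1, 0.5), 10)
  m2 <- suppressMessages(bipartitionMetrics(p, t2))
  expect_equal(m2$hammingLoss + mean(p == t2), 1)

  # degenerate label credited with the configurable convention
  pz <- cbind(c(1, 0), c(0, 0)); tz <- cbind(c(1, 1), c(0, 0))
  expect_message(mz <- bipartitionMetrics(pz, tz), "no positives")
  expect_equal(mz$perLabel$precision[2], 1)
  mz0 <- suppressMessages(bipartitionMetrics(pz, tz, emptyLabelValue = 0))
  expect_equal(mz0$perLabel$precision[2], 0)
})

test_that("random baseline AP hits forced and analytic cases", {
  # q = 1 all-positive truth: the single label is always at rank 1
  expect_equal(randomBaselineAP(matrix(1, 5, 1), trials = 3, seed = 1), 1)
  # all labels true: any ranking is perfect
  expect_equal(randomBaselineAP(matrix(1, 4, 3), trials = 3, seed = 1), 1)

  # single true label among q = 5: E[AP] = mean over ranks of 1/r
  set.seed(74)
  tr <- matrix(0, 100, 5)
  tr[cbind(1:100, sample(5, 100, replace = TRUE))] <- 1
  analytic <- mean(1 / (1:5))
  got <- randomBaselineAP(tr, trials = 200, seed = 9)
  perSampleSd <- sqrt(mean(1 / (1:5)^2) - analytic^2)
  expect_lt(abs(got - analytic), 3 * perSampleSd / sqrt(200 * 100))
})

test_that("fold assignment partitions instances into near-equal folds", {
  f <- foldAssignment(23, 5, seed = 3)
  expect_length(f, 23)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  expect_equal(foldAssignment(23, 5, seed = 3), f)
  expect_false(identical(foldAssignment(23, 5, seed = 4), f))
  expect_error(foldAssignment(3, 5), "n >= k")
})

test_that("cross-validation is deterministic and handles boundary cases", {
  ds <- smallDataset(n = 6, q = 2, seed = 41)
  # leave-one-out boundary
  loo <- kfoldCrossValidate(ds, modelSpecs = list(name = "brknn", k = 2),
                            k = 6, seed = 2)
  expect_true(all(is.finite(reportMetrics(loo))))
  expect_equal(sort(unique(loo@foldAssignment)), 1:6)

  r1 <- kfoldCrossValidate(ds, modelSpecs = list(name = "brknn", k = 2),
                           k = 3, seed = 7)
  r2 <- kfoldCrossValidate(ds, modelSpecs = list(name = "brknn", k = 2),
                           k = 3, seed = 7)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("a memorizing model on duplicated data reaches AP 1 per fold", {
  base <- smallDataset(n = 8, q = 2, seed = 43)
  dup <- MultiLabelDataset(
    ids = paste0("d", 1:16),
    sequences = rep(as.character(sequences(base)), 2),
    labels = rbind(labelMatrix(base), labelMatrix(base)),
    vocabulary = vocabulary(base))
  # memorization requires each instance's duplicate to sit in the training
  # fold; assert that precondition for the chosen fold seed, then the ceiling
  f <- foldAssignment(16, 2, seed = 10)
  expect_true(all(f[1:8] != f[9:16]))
  r <- kfoldCrossValidate(dup, modelSpecs = list(name = "brknn", k = 1),
                          k = 2, seed = 10)
  expect_equal(foldMetrics(r)$ap, rep(1, 2))
})

test_that("cross-validation survives folds with single-class labels", {
  ds <- smallDataset(n = 12, q = 2, seed = 47)
  Y <- labelMatrix(ds)
  Y[, 2] <- 0L; Y[1, 2] <- 1L  # one positive: most training folds degenerate
  rare <- MultiLabelDataset(ids = proteinIds(ds),
                            sequences = as.character(sequences(ds)),
                            labels = (Y + cbind(1 - pmax(Y[, 1], Y[, 2]), 0)),
                            vocabulary = vocabulary(ds))
  r <- kfoldCrossValidate(rare, modelSpecs = list(name = "iblr", k = 3),
                          k = 4, seed = 5)
  expect_true(all(is.finite(reportMetrics(r))))
})

test_that("min-max scaling is fit on training folds only", {
  ds <- smallDataset(n = 12, q = 2, seed = 53)
  r <- kfoldCrossValidate(ds, featureSpec = list(extractor = "188d",
                                                 scale = "minmax"),
                          modelSpecs = list(name = "brknn", k = 3),
                          k = 3, seed = 11)
  expect_true(all(is.finite(reportMetrics(r))))
})
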