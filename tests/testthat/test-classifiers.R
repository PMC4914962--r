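featureFixture <- function(n = 12, q = 3, seed = 3) {
  ds <- smallDataset(n = n, q = q, seed = seed)
  list(X = featurizeDataset(ds, "188d"), Y = labelMatrix(ds))
}

test_that("MLkNN priors and conditionals follow the smoothed closed forms", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("r", 1:4), NULL))
  Y <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 0L, 0L))
  m <- fitMLkNN(X, Y, k = 2, s = 1)
  expect_equal(unname(m$priors), c((1 + 2) / (2 + 4), (1 + 1) / (2 + 4)))

  Y0 <- cbind(a = rep(0L, 8), b = rep(1L, 8))
  X8 <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("r", 1:8), NULL))
  m0 <- fitMLkNN(X8, Y0, k = 2, s = 1)
  expect_equal(unname(m0$priors[1]), 1 / 10)  # smoothing floor

  expect_equal(rowSums(m$condPos), rep(1, 2), tolerance = 1e-9)
  expect_equal(rowSums(m$condNeg), rep(1, 2), tolerance = 1e-9)
  expect_error(fitMLkNN(X, Y, k = 4), "k < N")
})

test_that("MLkNN matches the brute-force counting oracle end to end", {
  set.seed(51)
  fx <- featureFixture(n = 12, q = 3, seed = 9)
  k <- 3; s <- 1
  m <- fitMLkNN(fx$X, fx$Y, k = k, s = s)
  o <- oracleMLkNN(fx$X, fx$Y, k = k, s = s)
  expect_equal(unname(m$priors), o$priors, tolerance = 1e-9)
  expect_equal(unname(m$condPos), o$condPos, tolerance = 1e-9)
  expect_equal(unname(m$condNeg), o$condNeg, tolerance = 1e-9)

  Xq <- matrix(rnorm(5 * ncol(fx$X), sd = 0.05), 5) +
    fx$X[rep(1:5, length.out = 5), ]
  p <- predictMLkNN(m, Xq)
  expect_equal(unname(p$scores), o$posterior(Xq), tolerance = 1e-9)
  expect_true(all(p$scores > 0 & p$scores < 1))
  expect_equal(unname(p$bipartition), unname((p$scores >= 0.5) * 1L))
})

test_that("MLkNN posterior is exactly 1/2 under full symmetry", {
  m <- structure(list(
    priors = 0.5,
    condPos = matrix(rep(1 / 3, 3), 1),
    condNeg = matrix(rep(1 / 3, 3), 1),
    X = matrix(c(0, 1, 2, 3), 4, 1, dimnames = list(paste0("r", 1:4), NULL)),
    Y = matrix(c(1L, 1L, 0L, 0L), 4, 1), k = 2, s = 1),
    class = "mlknnModel")
  p <- predictMLkNN(m, matrix(c(0.4, 2.6), 2, 1))
  expect_equal(unname(p$scores), matrix(0.5, 2, 1))
})

test_that("BRkNN scores are neighbor label frequencies", {
  fx <- featureFixture(n = 10, q = 2, seed = 13)
  set.seed(52)
  Xq <- fx$X + matrix(rnorm(length(fx$X), sd = 0.02), nrow(fx$X))
  p <- fitPredictBRkNN(fx$X, fx$Y, Xq, k = 3, variant = "raw")
  expect_equal(unname(p$scores), oracleBRkNN(fx$X, fx$Y, Xq, 3),
               tolerance = 1e-9)

  # k = 1: prediction copies the nearest neighbor's label set
  p1 <- fitPredictBRkNN(fx$X, fx$Y, fx$X, k = 1)
  expect_equal(unname(p1$bipartition), unname(fx$Y))

  # all k neighbors sharing a label force its score to 1
  Yall <- cbind(rep(1L, 10), fx$Y[, 2])
  pAll <- fitPredictBRkNN(fx$X, Yall, Xq, k = 3)
  expect_true(all(pAll$scores[, 1] == 1))

  expect_error(fitPredictBRkNN(fx$X, fx$Y, Xq, k = 11), "k <= N")
})

test_that("BRkNN variant 'a' outputs the top label instead of an empty set", {
  X <- matrix(c(0, 1, 2, 10), 4, 1, dimnames = list(paste0("r", 1:4), NULL))
  # query at 1.4: neighbors are rows 2, 3, 1; each label gets score 1/3
  Y2 <- cbind(a = c(1L, 0L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
              c = c(0L, 0L, 1L, 1L))
  pr <- fitPredictBRkNN(X, Y2, matrix(1.4), k = 3, variant = "raw")
  expect_true(all(pr$scores == 1 / 3))
  expect_equal(sum(pr$bipartition), 0)
  pa <- fitPredictBRkNN(X, Y2, matrix(1.4), k = 3, variant = "a")
  expect_equal(unname(pa$bipartition[1, ]), c(1L, 0L, 0L))  # tie -> lowest
})

test_that("IBLR-ML behaves on symmetric, separable and degenerate labels", {
  fx <- featureFixture(n = 20, q = 3, seed = 17)
  # duplicated label column: identical ranking of instances
  Y <- cbind(fx$Y, dup = fx$Y[, 1])
  m <- fitIBLR(fx$X, Y, k = 5)
  p <- predictIBLR(m, fx$X)
  expect_equal(order(p$scores[, 1]), order(p$scores[, 4]))

  # degenerate label: empirical prior with a warning
  Yd <- cbind(fx$Y, never = rep(0L, 20))
  expect_warning(md <- fitIBLR(fx$X, Yd, k = 5), "single class")
  pd <- predictIBLR(md, fx$X)
  expect_true(all(pd$scores[, 4] == 0))
})

test_that("IBLR-ML probabilities agree with a hand-rolled IRLS oracle", {
  ds <- smallDataset(n = 20, q = 2, seed = 19, effectSize = 1)
  fx <- list(X = featurizeDataset(ds, "188d"), Y = labelMatrix(ds))
  k <- 5
  m <- fitIBLR(fx$X, fx$Y, k = k)
  p <- predictIBLR(m, fx$X)
  # rebuild the meta-features independently: LOO neighbor frequencies
  ids <- rownames(fx$X)
  dists <- as.matrix(dist(fx$X))
  Fmeta <- t(vapply(1:20, function(i) {
    d <- dists[i, ]; d[i] <- Inf
    nn <- order(d, ids)[1:k]
    colSums(fx$Y[nn, , drop = FALSE]) / k
  }, numeric(2)))
  Fq <- t(vapply(1:20, function(m2) {
    d <- dists[m2, ]
    nn <- order(d, ids)[1:k]
    colSums(fx$Y[nn, , drop = FALSE]) / k
  }, numeric(2)))
  for (j in 1:2) {
    ora <- oracleIRLS(Fmeta, fx$Y[, j])
    expect_equal(unname(p$scores[, j]), ora(Fq), tolerance = 1e-4)
  }
})

test_that("binary relevance covers degenerate labels and memorizing kNN", {
  fx <- featureFixture(n = 14, q = 2, seed = 23)
  Y <- cbind(fx$Y, never = rep(0L, 14), always = rep(1L, 14))
  m <- fitBinaryRelevance(fx$X, Y, base = "tree")
  p <- predictBinaryRelevance(m, fx$X)
  expect_true(all(p$scores[, 3] == 0))
  expect_true(all(p$scores[, 4] == 1))
  expect_true(all(p$scores >= 0 & p$scores <= 1))

  # 1-NN on training queries reproduces the training labels
  m1 <- fitBinaryRelevance(fx$X, fx$Y, base = "knn", k = 1)
  p1 <- predictBinaryRelevance(m1, fx$X)
  expect_equal(unname(p1$bipartition), unname(fx$Y))

  # q = 1 works and matches a directly fitted learner's shape
  mq <- fitBinaryRelevance(fx$X, fx$Y[, 1, drop = FALSE], base = "logistic")
  pq <- predictBinaryRelevance(mq, fx$X)
  expect_equal(dim(pq$scores), c(14, 1))

  expect_error(fitBinaryRelevance(fx$X, fx$Y, base = "svm"))
})

test_that("forest base learner is seeded and probabilistic", {
  fx <- featureFixture(n = 16, q = 2, seed = 29)
  m1 <- fitBinaryRelevance(fx$X, fx$Y, base = "forest", ntree = 30, seed = 7)
  m2 <- fitBinaryRelevance(fx$X, fx$Y, base = "forest", ntree = 30, seed = 7)
  p1 <- predictBinaryRelevance(m1, fx$X)
  p2 <- predictBinaryRelevance(m2, fx$X)
  expect_equal(p1$scores, p2$scores)
  expect_true(all(p1$scores >= 0 & p1$scores <= 1))
})

test_that("training-instance order never changes a prediction", {
  fx <- featureFixture(n = 15, q = 3, seed = 31)
  set.seed(53)
  Xq <- fx$X[1:4, ] + matrix(rnorm(4 * ncol(fx$X), sd = 0.01), 4)
  perm <- sample(15)
  Xp <- fx$X[perm, ]; Yp <- fx$Y[perm, ]

  m <- fitMLkNN(fx$X, fx$Y, k = 4)
  mp <- fitMLkNN(Xp, Yp, k = 4)
  expect_equal(predictMLkNN(m, Xq)$scores, predictMLkNN(mp, Xq)$scores)

  expect_equal(fitPredictBRkNN(fx$X, fx$Y, Xq, k = 4)$scores,
               fitPredictBRkNN(Xp, Yp, Xq, k = 4)$scores)
})

test_that("spec-driven interface dispatches and validates model names", {
  fx <- featureFixture(n = 12, q = 2, seed = 37)
  for (spec in list(list(name = "mlknn", k = 3), list(name = "brknn", k = 3),
                    list(name = "iblr", k = 3),
                    list(name = "br", base = "tree"))) {
    m <- suppressWarnings(fitModel(spec, fx$X, fx$Y))
    p <- predictModel(m, fx$X, minOneLabel = TRUE)
    expect_true(all(p$scores >= 0 & p$scores <= 1), info = spec$name)
    expect_true(all(rowSums(p$bipartition) >= 1), info = spec$name)
  }
  expect_error(fitModel(list(name = "homer"), fx$X, fx$Y), "unknown model")
})
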