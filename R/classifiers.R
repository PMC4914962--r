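# Instance-based multi-label classifiers. All neighbor searches use
# Euclidean distance with deterministic tie-breaking by (distance, training
# id), so permuting the training order never changes a prediction.

euclideanDistances <- function(Q, X) {
  # M x N matrix of distances between query rows and training rows
  d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# returns an M x k matrix of training-row indices; ties at equal distance are
# broken by training id (rownames of X, falling back to row number)
kNearestNeighbors <- function(X, Q, k, excludeSelf = FALSE) {
  if (k > nrow(X) - excludeSelf)
    stop("k = ", k, " exceeds the number of available training instances")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("row%09d", seq_len(nrow(X)))
  D <- euclideanDistances(Q, X)
  res <- vapply(seq_len(nrow(Q)), function(m) {
    d <- D[m, ]
    if (excludeSelf) d[m] <- Inf
    order(d, ids)[seq_len(k)]
  }, integer(k))
  # vapply drops to a vector when k = 1
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

asBinaryMatrix <- function(Y) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "integer"
  if (length(Y) && !all(Y %in% c(0L, 1L)))
    stop("label matrix must be binary")
  Y
}

bipartitionFrom <- function(scores, threshold = 0.5, minOneLabel = FALSE) {
  bip <- (scores >= threshold) * 1L
  if (minOneLabel && ncol(scores) > 0) {
    empty <- which(rowSums(bip) == 0)
    for (i in empty) bip[i, which.max(scores[i, ])] <- 1L
  }
  bip
}

# ---------------------------------------------------------------------------
# MLkNN

#' Fit a multi-label k-nearest-neighbor (MLkNN) model
#'
#' MLkNN applies a per-label Bayes rule to the number of a query's k nearest
#' neighbors carrying the label. Priors are Laplace-smoothed label
#' frequencies, P(H_j) = (s + sum_i Y_ij) / (2s + N); the count-conditional
#' likelihoods P(c | H_j) and P(c | not H_j) are estimated from leave-one-out
#' neighbor membership counts on the training set, smoothed over the k+1
#' count bins.
#'
#' @param X numeric N x d feature matrix (rownames used as tie-break ids).
#' @param Y binary N x q label matrix.
#' @param k neighborhood size (default 10); requires N >= k + 1.
#' @param s Laplace smoothing constant (> 0, default 1).
#' @return An object of class `mlknnModel` with elements `priors` (q),
#'   `condPos`/`condNeg` (q x (k+1), rows summing to 1), `X`, `Y`, `k`, `s`.
#' @export
fitMLkNN <- function(X, Y, k = 10, s = 1) {
  X <- as.matrix(X); Y <- asBinaryMatrix(Y)
  N <- nrow(X); q <- ncol(Y)
  stopifnot(nrow(Y) == N, s > 0)
  if (k >= N) stop("MLkNN requires k < N (k = ", k, ", N = ", N, ")")
  priors <- (s + colSums(Y)) / (2 * s + N)
  nn <- kNearestNeighbors(X, X, k, excludeSelf = TRUE)
  condPos <- matrix(0, q, k + 1)
  condNeg <- matrix(0, q, k + 1)
  for (j in seq_len(q)) {
    cj <- vapply(seq_len(N), function(i) sum(Y[nn[i, ], j]), integer(1))
    for (c0 in 0:k) {
      condPos[j, c0 + 1] <- sum(cj == c0 & Y[, j] == 1)
      condNeg[j, c0 + 1] <- sum(cj == c0 & Y[, j] == 0)
    }
  }
  condPos <- (condPos + s) / (rowSums(condPos) + s * (k + 1))
  condNeg <- (condNeg + s) / (rowSums(condNeg) + s * (k + 1))
  structure(list(priors = priors, condPos = condPos, condNeg = condNeg,
                 X = X, Y = Y, k = k, s = s),
            class = "mlknnModel")
}

#' Predict with an MLkNN model
#'
#' For each query and label j, with c = number of the k nearest training
#' neighbors carrying j, the score is the posterior
#' P(H_j) P(c|H_j) / (P(H_j) P(c|H_j) + P(not H_j) P(c|not H_j)); the
#' bipartition thresholds the score at 0.5.
#'
#' @param model an `mlknnModel` from [fitMLkNN()].
#' @param Xq numeric M x d query matrix.
#' @param minOneLabel force the top-scoring label when a query's threshold
#'   set would be empty (default FALSE).
#' @return list with `scores` (M x q in (0,1)) and `bipartition` (M x q).
#' @export
predictMLkNN <- function(model, Xq, minOneLabel = FALSE) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(model$X))
    stop("query feature dimension (", ncol(Xq), ") does not match model (",
         ncol(model$X), ")")
  q <- ncol(model$Y)
  nn <- kNearestNeighbors(model$X, Xq, model$k)
  scores <- matrix(0, nrow(Xq), q, dimnames = list(NULL, colnames(model$Y)))
  for (j in seq_len(q)) {
    cj <- vapply(seq_len(nrow(Xq)), function(m) sum(model$Y[nn[m, ], j]),
                 integer(1))
    pPos <- model$priors[j] * model$condPos[j, cj + 1]
    pNeg <- (1 - model$priors[j]) * model$condNeg[j, cj + 1]
    scores[, j] <- pPos / (pPos + pNeg)
  }
  list(scores = scores,
       bipartition = bipartitionFrom(scores, 0.5, minOneLabel))
}

# ---------------------------------------------------------------------------
# BRkNN

#' Binary-relevance k-nearest-neighbor (BRkNN) prediction
#'
#' Scores each label by its frequency among the query's k nearest training
#' neighbors; the bipartition thresholds at 0.5. The `"a"` variant avoids
#' empty predictions: when no label reaches 0.5 the single top-scoring label
#' is output (score ties resolved to the lowest column index).
#'
#' @param X,Y training features and binary labels (N >= k).
#' @param Xq query feature matrix.
#' @param k neighborhood size, default 10.
#' @param variant `"a"` (default) or `"raw"`.
#' @return list with `scores` and `bipartition` (both M x q).
#' @export
fitPredictBRkNN <- function(X, Y, Xq, k = 10, variant = c("a", "raw")) {
  variant <- match.arg(variant)
  X <- as.matrix(X); Y <- asBinaryMatrix(Y); Xq <- as.matrix(Xq)
  if (k > nrow(X)) stop("BRkNN requires k <= N (k = ", k, ", N = ",
                        nrow(X), ")")
  nn <- kNearestNeighbors(X, Xq, k)
  scores <- t(vapply(seq_len(nrow(Xq)),
                     function(m) colSums(Y[nn[m, ], , drop = FALSE]) / k,
                     numeric(ncol(Y))))
  if (ncol(Y) == 1) scores <- matrix(scores, ncol = 1)
  colnames(scores) <- colnames(Y)
  bip <- (scores >= 0.5) * 1L
  if (variant == "a") {
    empty <- which(rowSums(bip) == 0)
    for (i in empty) bip[i, which.max(scores[i, ])] <- 1L
  }
  list(scores = scores, bipartition = bip)
}

# leave-one-out neighbor label frequencies (meta-features for IBLR-ML)
looNeighborFrequencies <- function(X, Y, k) {
  nn <- kNearestNeighbors(X, X, k, excludeSelf = TRUE)
  f <- t(vapply(seq_len(nrow(X)),
                function(i) colSums(Y[nn[i, ], , drop = FALSE]) / k,
                numeric(ncol(Y))))
  if (ncol(Y) == 1) f <- matrix(f, ncol = 1)
  f
}

# ---------------------------------------------------------------------------
# IBLR-ML

#' Fit an instance-based logistic regression (IBLR-ML) model
#'
#' For each label j, a logistic model is fit by maximum likelihood on
#' meta-features: the q per-label neighbor frequencies (computed
#' leave-one-out on the training set, as in BRkNN) predicting Y_j. This lets
#' each label's model exploit the local evidence for *all* labels, capturing
#' label correlations.
#'
#' A label with no positive (or no negative) training examples cannot
#' support a logistic fit; its model degenerates to the empirical prior with
#' a warning.
#'
#' @param X,Y training features and binary labels (N >= k + 1).
#' @param k neighborhood size, default 10.
#' @return An object of class `iblrModel`.
#' @export
fitIBLR <- function(X, Y, k = 10) {
  X <- as.matrix(X); Y <- asBinaryMatrix(Y)
  if (k >= nrow(X)) stop("IBLR-ML requires k < N")
  Fmeta <- looNeighborFrequencies(X, Y, k)
  q <- ncol(Y)
  models <- vector("list", q)
  for (j in seq_len(q)) {
    yj <- Y[, j]
    colnames(Fmeta) <- paste0("X", seq_len(q))
    if (all(yj == 1) || all(yj == 0)) {
      warning("label ", j, " has a single class; using the empirical prior")
      models[[j]] <- list(constant = mean(yj))
    } else {
      df <- data.frame(y = yj, Fmeta)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      models[[j]] <- list(fit = fit)
    }
  }
  structure(list(models = models, X = X, Y = Y, k = k,
                 labels = colnames(Y)),
            class = "iblrModel")
}

#' Predict with an IBLR-ML model
#'
#' Computes the query's q neighbor label frequencies over the training set
#' and applies each label's logistic model; the bipartition thresholds at
#' 0.5.
#'
#' @param model an `iblrModel` from [fitIBLR()].
#' @param Xq query feature matrix.
#' @param minOneLabel force the top label when the set would be empty.
#' @return list with `scores` and `bipartition`.
#' @export
predictIBLR <- function(model, Xq, minOneLabel = FALSE) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(model$X))
    stop("query feature dimension does not match model")
  nn <- kNearestNeighbors(model$X, Xq, model$k)
  Fq <- t(vapply(seq_len(nrow(Xq)),
                 function(m) colSums(model$Y[nn[m, ], , drop = FALSE]) /
                   model$k,
                 numeric(ncol(model$Y))))
  if (ncol(model$Y) == 1) Fq <- matrix(Fq, ncol = 1)
  q <- length(model$models)
  scores <- matrix(0, nrow(Xq), q, dimnames = list(NULL, model$labels))
  newdata <- as.data.frame(Fq)
  names(newdata) <- paste0("X", seq_len(q))
  for (j in seq_len(q)) {
    mj <- model$models[[j]]
    scores[, j] <- if (!is.null(mj$constant)) mj$constant else
      suppressWarnings(predict(mj$fit, newdata = newdata, type = "response"))
  }
  list(scores = scores,
       bipartition = bipartitionFrom(scores, 0.5, minOneLabel))
}

# ---------------------------------------------------------------------------
# Binary relevance over single-label base learners

#' Fit a binary-relevance multi-label model
#'
#' Trains one independent probabilistic binary classifier per label. Base
#' learners: `"tree"` (recursive partitioning via rpart), `"forest"`
#' (random forest), `"logistic"` (penalized-free binomial GLM on the raw
#' features) and `"knn"` (neighbor vote fraction). A label whose training
#' set is single-class degenerates to the constant score 0 or 1.
#'
#' @param X,Y training features and binary labels.
#' @param base base learner name.
#' @param k neighborhood size for the `"knn"` base learner.
#' @param ntree number of trees for the `"forest"` learner.
#' @param seed integer seed for stochastic learners.
#' @return An object of class `brModel`.
#' @export
fitBinaryRelevance <- function(X, Y,
                               base = c("tree", "knn", "forest", "logistic"),
                               k = 5, ntree = 100, seed = 1) {
  base <- match.arg(base)
  X <- as.matrix(X); Y <- asBinaryMatrix(Y)
  q <- ncol(Y)
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  models <- vector("list", q)
  for (j in seq_len(q)) {
    yj <- Y[, j]
    if (all(yj == 1) || all(yj == 0)) {
      models[[j]] <- list(constant = yj[1])
      next
    }
    models[[j]] <- switch(base,
      tree = {
        fit <- rpart::rpart(y ~ ., data = cbind(y = factor(yj, c(0, 1)), df),
                            method = "class")
        list(fit = fit)
      },
      forest = {
        set.seed(seed + j)
        fit <- randomForest::randomForest(x = df, y = factor(yj, c(0, 1)),
                                          ntree = ntree)
        list(fit = fit)
      },
      logistic = {
        fit <- suppressWarnings(glm(y ~ ., data = cbind(y = yj, df),
                                    family = binomial()))
        list(fit = fit)
      },
      knn = list(knn = TRUE))
  }
  structure(list(models = models, base = base, X = X, Y = Y, k = k,
                 labels = colnames(Y), featureNames = names(df)),
            class = "brModel")
}

#' Predict with a binary-relevance model
#'
#' @param model a `brModel` from [fitBinaryRelevance()].
#' @param Xq query feature matrix.
#' @param minOneLabel force the top label when the set would be empty.
#' @return list with `scores` (per-label positive-class probabilities) and
#'   `bipartition` (threshold 0.5).
#' @export
predictBinaryRelevance <- function(model, Xq, minOneLabel = FALSE) {
  Xq <- as.matrix(Xq)
  if (ncol(Xq) != ncol(model$X))
    stop("query feature dimension does not match model")
  df <- as.data.frame(Xq)
  names(df) <- model$featureNames
  q <- length(model$models)
  scores <- matrix(0, nrow(Xq), q, dimnames = list(NULL, model$labels))
  knnNN <- NULL
  for (j in seq_len(q)) {
    mj <- model$models[[j]]
    scores[, j] <- if (!is.null(mj$constant)) {
      as.numeric(mj$constant)
    } else if (!is.null(mj$knn)) {
      if (is.null(knnNN))
        knnNN <- kNearestNeighbors(model$X, Xq, min(model$k, nrow(model$X)))
      vapply(seq_len(nrow(Xq)),
             function(m) mean(model$Y[knnNN[m, ], j]), numeric(1))
    } else if (model$base == "tree") {
      predict(mj$fit, newdata = df, type = "prob")[, "1"]
    } else if (model$base == "forest") {
      predict(mj$fit, newdata = df, type = "prob")[, "1"]
    } else {
      suppressWarnings(predict(mj$fit, newdata = df, type = "response"))
    }
  }
  list(scores = scores,
       bipartition = bipartitionFrom(scores, 0.5, minOneLabel))
}

# ---------------------------------------------------------------------------
# Generic spec-driven interface used by the cross-validation driver

#' Fit a multi-label model from a specification list
#'
#' Dispatches on `spec$name` in \{"mlknn", "brknn", "iblr", "br"\}; remaining
#' list entries are hyperparameters (`k`, `s`, `variant`, `base`, `ntree`,
#' `seed`). BRkNN is lazy, so its "model" stores the training data.
#'
#' @param spec named list, e.g. `list(name = "mlknn", k = 10, s = 1)`.
#' @param X,Y training features and binary labels.
#' @return A fitted model usable with [predictModel()].
#' @export
fitModel <- function(spec, X, Y) {
  name <- spec$name
  k <- if (is.null(spec$k)) 10 else spec$k
  switch(name,
    mlknn = fitMLkNN(X, Y, k = k, s = if (is.null(spec$s)) 1 else spec$s),
    brknn = structure(list(X = as.matrix(X), Y = asBinaryMatrix(Y), k = k,
                           variant = if (is.null(spec$variant)) "a" else
                             spec$variant),
                      class = "brknnModel"),
    iblr = fitIBLR(X, Y, k = k),
    br = fitBinaryRelevance(X, Y,
                            base = if (is.null(spec$base)) "tree" else
                              spec$base,
                            k = if (is.null(spec$k)) 5 else spec$k,
                            ntree = if (is.null(spec$ntree)) 100 else
                              spec$ntree,
                            seed = if (is.null(spec$seed)) 1 else spec$seed),
    stop("unknown model name: ", name))
}

#' Predict from a model fitted by [fitModel()]
#'
#' @param model fitted model.
#' @param Xq query feature matrix.
#' @param minOneLabel force a non-empty prediction set.
#' @return list with `scores` and `bipartition`.
#' @export
predictModel <- function(model, Xq, minOneLabel = FALSE) {
  if (inherits(model, "mlknnModel")) {
    predictMLkNN(model, Xq, minOneLabel)
  } else if (inherits(model, "brknnModel")) {
    out <- fitPredictBRkNN(model$X, model$Y, Xq, k = model$k,
                           variant = model$variant)
    if (minOneLabel)
      out$bipartition <- bipartitionFrom(out$scores, 0.5, TRUE)
    out
  } else if (inherits(model, "iblrModel")) {
    predictIBLR(model, Xq, minOneLabel)
  } else if (inherits(model, "brModel")) {
    predictBinaryRelevance(model, Xq, minOneLabel)
  } else stop("not a fitted SubLocML model")
}
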