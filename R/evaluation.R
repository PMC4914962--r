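# Ranking and bipartition metrics for multi-label prediction, and the
# seeded k-fold cross-validation driver.

#' Ranking average precision (AP)
#'
#' For each instance i with true label set y_i, labels are ranked by
#' descending score and
#' AP_i = (1/|y_i|) * sum over true labels l of
#' |\{l' in y_i : rank(l') <= rank(l)\}| / rank(l). Score ties use the
#' counting convention: rank(l) is the number of labels scoring at least
#' score(l), and the numerator counts true labels the same way, so ties
#' among true labels never push AP above 1. The reported AP is the mean over
#' instances; AP = 1 exactly when every true label strictly outranks every
#' false label (ties among true labels allowed). Instances with no true
#' label are excluded from the mean with a message.
#'
#' @param scores numeric N x q matrix of prediction scores.
#' @param truth binary N x q matrix.
#' @return AP in \[0, 1\].
#' @export
#' @examples
#' averagePrecision(matrix(c(0.9, 0.2, 0.5), 1), matrix(c(1, 1, 0), 1))
averagePrecision <- function(scores, truth) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth)))
    stop("scores and truth must have the same shape")
  keep <- rowSums(truth) >= 1
  if (any(!keep))
    message("averagePrecision: excluding ", sum(!keep),
            " instance(s) with no true label")
  idx <- which(keep)
  if (!length(idx)) stop("no instance with a true label")
  ap <- vapply(idx, function(i) {
    s <- scores[i, ]
    st <- s[truth[i, ] == 1]
    mean(vapply(st, function(sl) {
      rl <- sum(s >= sl)        # rank of l = labels scoring at least it
      sum(st >= sl) / rl        # true labels at or above l, same convention
    }, numeric(1)))
  }, numeric(1))
  mean(ap)
}

#' Bipartition (hard-prediction) metrics
#'
#' Hamming loss is the fraction of instance-label cells where prediction and
#' truth disagree; micro metrics pool TP/FP/FN over all labels; macro
#' metrics average per-label values. A label with no positive predictions
#' and no positives in truth contributes precision/recall/F of
#' `emptyLabelValue` (default 1, the optimistic convention, reported with a
#' message). Subset accuracy is the fraction of rows with an exact set
#' match.
#'
#' @param pred,truth binary N x q matrices.
#' @param emptyLabelValue value credited to a label with TP = FP = FN = 0.
#' @return Named list: `hammingLoss`, `subsetAccuracy`, `macroPrecision`,
#'   `macroRecall`, `macroF`, `microPrecision`, `microRecall`, `microF`,
#'   and `perLabel` (data.frame).
#' @export
bipartitionMetrics <- function(pred, truth, emptyLabelValue = 1) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape")
  q <- ncol(truth)
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  degenerate <- (tp + fp + fn) == 0
  if (any(degenerate))
    message("bipartitionMetrics: ", sum(degenerate),
            " label(s) with no positives in truth or prediction")
  prec <- ifelse(tp + fp > 0, tp / (tp + fp),
                 ifelse(degenerate, emptyLabelValue, 0))
  rec <- ifelse(tp + fn > 0, tp / (tp + fn),
                ifelse(degenerate, emptyLabelValue, 0))
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  f[degenerate] <- emptyLabelValue
  microP <- if (sum(tp + fp) > 0) sum(tp) / sum(tp + fp) else emptyLabelValue
  microR <- if (sum(tp + fn) > 0) sum(tp) / sum(tp + fn) else emptyLabelValue
  microF <- if (microP + microR > 0) 2 * microP * microR / (microP + microR)
            else 0
  perLabel <- data.frame(
    label = if (!is.null(colnames(truth))) colnames(truth) else
      paste0("label", seq_len(q)),
    tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f = f,
    row.names = NULL)
  list(
    hammingLoss = mean(pred != truth),
    subsetAccuracy = mean(rowSums(pred != truth) == 0),
    macroPrecision = mean(prec), macroRecall = mean(rec), macroF = mean(f),
    microPrecision = microP, microRecall = microR, microF = microF,
    perLabel = perLabel)
}

#' Mean AP of random rankings against a truth matrix
#'
#' Monte-Carlo reference point: the mean [averagePrecision()] of uniformly
#' random score matrices against `truth` over `trials` replicates.
#'
#' @param truth binary N x q matrix.
#' @param trials number of random score matrices, default 100.
#' @param seed RNG seed.
#' @return Numeric baseline AP.
#' @export
randomBaselineAP <- function(truth, trials = 100, seed = 1) {
  stopifnot(trials >= 1)
  truth <- as.matrix(truth)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mean(vapply(seq_len(trials), function(t)
    suppressMessages(
      averagePrecision(matrix(runif(length(truth)), nrow(truth)), truth)),
    numeric(1)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Seeded k-fold assignment
#'
#' Plain seeded shuffle into k near-equal folds (not label-stratified,
#' mirroring a protocol that leaves stratification unstated).
#'
#' @param n number of instances.
#' @param k number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k, one per instance.
#' @export
foldAssignment <- function(n, k, seed = 42) {
  stopifnot(k >= 2, n >= k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  folds <- integer(n)
  folds[sample.int(n)] <- rep(seq_len(k), times = sizes)
  folds
}

#' k-fold cross-validation of one or several multi-label models
#'
#' For each fold the dataset is featurized, every model spec is fit on the
#' k-1 training folds and scored on the held-out fold, the P score matrices
#' are fused with the requested ensemble strategy (or passed through when a
#' single model and no ensemble are given), and metrics are computed. The
#' report aggregates metrics over the concatenated held-out predictions and
#' keeps per-fold values and the fold assignment for reproducibility.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param featureSpec named list with `extractor` and extractor arguments
#'   (see [featurizeDataset()]); `scale = "minmax"` requests per-column
#'   min-max scaling fit on the training folds only.
#' @param modelSpecs list of model specification lists (see [fitModel()]);
#'   a single spec may be passed directly.
#' @param ensemble `NULL`, `"mean"`, `"majority"` or `"topk"`.
#' @param K top-K parameter when `ensemble = "topk"`.
#' @param k number of folds, default 5.
#' @param seed RNG seed for the fold shuffle and stochastic learners.
#' @param pssms named list id -> [PSSMProfile-class] for PSSM extractors.
#' @param minOneLabel force non-empty predicted label sets (default TRUE,
#'   for fair accuracy comparison on single-label data).
#' @return An [EvaluationReport-class].
#' @export
kfoldCrossValidate <- function(dataset, featureSpec = list(extractor = "188d"),
                               modelSpecs = list(list(name = "brknn")),
                               ensemble = NULL, K = NULL, k = 5, seed = 42,
                               pssms = NULL, minOneLabel = TRUE) {
  if (!is.null(modelSpecs$name)) modelSpecs <- list(modelSpecs)
  n <- length(dataset)
  Y <- labelMatrix(dataset)
  X <- featurizeDataset(dataset,
                        extractor = featureSpec$extractor,
                        pssms = pssms,
                        lam = if (is.null(featureSpec$lam)) 4 else
                          featureSpec$lam,
                        w = if (is.null(featureSpec$w)) 0.05 else
                          featureSpec$w,
                        normalize = if (is.null(featureSpec$normalize))
                          "logistic" else featureSpec$normalize)
  folds <- foldAssignment(n, k, seed)
  scale <- identical(featureSpec$scale, "minmax")

  allScores <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  allBip <- matrix(NA_integer_, n, ncol(Y))
  foldRows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale) {
      lo <- apply(Xtr, 2, min); hi <- apply(Xtr, 2, max)
      rng <- ifelse(hi > lo, hi - lo, 1)
      Xtr <- sweep(sweep(Xtr, 2, lo), 2, rng, "/")
      Xte <- pmin(pmax(sweep(sweep(Xte, 2, lo), 2, rng, "/"), 0), 1)
    }
    Ytr <- Y[tr, , drop = FALSE]
    preds <- lapply(seq_along(modelSpecs), function(p) {
      spec <- modelSpecs[[p]]
      if (spec$name == "br" && is.null(spec$seed)) spec$seed <- seed + f
      m <- suppressWarnings(fitModel(spec, Xtr, Ytr))
      predictModel(m, Xte, minOneLabel = minOneLabel)
    })
    if (length(preds) == 1 && is.null(ensemble)) {
      sc <- preds[[1]]$scores
      bip <- preds[[1]]$bipartition
    } else {
      strategy <- if (is.null(ensemble)) "mean" else ensemble
      fused <- fuseScores(lapply(preds, `[[`, "scores"), strategy, K)
      sc <- fused$scores01
      bip <- fused$bipartition
      if (minOneLabel) {
        empty <- which(rowSums(bip) == 0)
        for (i in empty) bip[i, which.max(sc[i, ])] <- 1L
      }
    }
    allScores[te, ] <- sc
    allBip[te, ] <- bip
    bm <- suppressMessages(bipartitionMetrics(bip, Y[te, , drop = FALSE]))
    foldRows[[f]] <- data.frame(
      fold = f,
      ap = suppressMessages(averagePrecision(sc, Y[te, , drop = FALSE])),
      hammingLoss = bm$hammingLoss, subsetAccuracy = bm$subsetAccuracy,
      macroPrecision = bm$macroPrecision, microPrecision = bm$microPrecision,
      macroF = bm$macroF, microF = bm$microF)
  }
  foldDf <- do.call(rbind, foldRows)
  bm <- suppressMessages(bipartitionMetrics(allBip, Y))
  metrics <- c(
    ap = suppressMessages(averagePrecision(allScores, Y)),
    hammingLoss = bm$hammingLoss, subsetAccuracy = bm$subsetAccuracy,
    macroPrecision = bm$macroPrecision, macroRecall = bm$macroRecall,
    macroF = bm$macroF, microPrecision = bm$microPrecision,
    microRecall = bm$microRecall, microF = bm$microF)
  new("EvaluationReport", metrics = metrics, perLabel = bm$perLabel,
      folds = foldDf, foldAssignment = as.integer(folds))
}
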