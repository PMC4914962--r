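# Ensemble voting strategies fusing the outputs of P base multi-label
# classifiers over a shared label vocabulary.

checkScoreList <- function(scores) {
  if (!length(scores)) stop("need at least one score matrix")
  scores <- lapply(scores, as.matrix)
  dims <- vapply(scores, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("score matrices have mismatching shapes")
  for (m in scores)
    if (length(m) && (min(m) < 0 || max(m) > 1))
      stop("scores must lie in [0, 1]")
  scores
}

#' Mean-vote ensemble
#'
#' Fuses P probabilistic score matrices by the per-cell arithmetic mean; a
#' label is predicted when the fused probability reaches 0.5 (the boundary
#' belongs to the positive class).
#'
#' @param scores list of P numeric N x q score matrices in \[0, 1\].
#' @return list with `fused` (N x q), `bipartition`, `strategy = "mean"`.
#' @export
#' @examples
#' meanEnsemble(list(matrix(c(0.6, 0.2), 1), matrix(c(0.8, 0.4), 1)))
meanEnsemble <- function(scores) {
  scores <- checkScoreList(scores)
  fused <- Reduce(`+`, scores) / length(scores)
  list(fused = fused, bipartition = (fused >= 0.5) * 1L, strategy = "mean")
}

#' Majority-vote ensemble
#'
#' Each base classifier votes +1 (positive) or -1 (counterexample) per cell;
#' the fused value is the mean vote in \[-1, 1\] and a label is predicted
#' when the fused vote is >= 0 (an exact tie counts as positive).
#'
#' @param votes list of P matrices with entries in \{-1, +1\}.
#' @return list with `fused`, `bipartition`, `strategy = "majority"`.
#' @export
majorityVoteEnsemble <- function(votes) {
  if (!length(votes)) stop("need at least one vote matrix")
  votes <- lapply(votes, as.matrix)
  dims <- vapply(votes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("vote matrices have mismatching shapes")
  for (m in votes)
    if (length(m) && !all(m %in% c(-1, 1)))
      stop("votes must be -1 or +1")
  fused <- Reduce(`+`, votes) / length(votes)
  list(fused = fused, bipartition = (fused >= 0) * 1L,
       strategy = "majority")
}

#' Top-K ensemble
#'
#' For each cell the P classifier scores are sorted descending and the mean
#' of the first K is the fused value; the bipartition thresholds at 0.5.
#' K = P recovers [meanEnsemble()] exactly; K = 1 is the per-cell maximum.
#'
#' @param scores list of P score matrices in \[0, 1\].
#' @param K how many of the top-ranked scores to average, 1 <= K <= P;
#'   default ceiling(P / 2).
#' @return list with `fused`, `bipartition`, `strategy = "topk"`, `K`.
#' @export
topKEnsemble <- function(scores, K = NULL) {
  scores <- checkScoreList(scores)
  P <- length(scores)
  if (is.null(K)) K <- ceiling(P / 2)
  if (K < 1 || K > P) stop("K must satisfy 1 <= K <= P (K = ", K,
                           ", P = ", P, ")")
  arr <- array(unlist(scores), dim = c(dim(scores[[1]]), P))
  fused <- apply(arr, c(1, 2), function(v) mean(sort(v, decreasing = TRUE)[seq_len(K)]))
  if (!is.matrix(fused)) fused <- matrix(fused, dim(scores[[1]])[1])
  dimnames(fused) <- dimnames(scores[[1]])
  list(fused = fused, bipartition = (fused >= 0.5) * 1L,
       strategy = "topk", K = K)
}

#' Convert probabilistic scores to hard votes
#'
#' Bridges probabilistic learners into the +/-1 voting scheme: +1 where the
#' score reaches the threshold, else -1.
#'
#' @param scores numeric score matrix.
#' @param threshold decision threshold, default 0.5.
#' @return Matrix of the same shape with entries in \{-1, +1\}.
#' @export
scoresToVotes <- function(scores, threshold = 0.5) {
  scores <- as.matrix(scores)
  v <- ifelse(scores >= threshold, 1, -1)
  dimnames(v) <- dimnames(scores)
  v
}

#' Apply an ensemble strategy specification to base-classifier scores
#'
#' @param scores list of P score matrices.
#' @param strategy `"mean"`, `"majority"` or `"topk"`.
#' @param K top-K parameter (topk only).
#' @return Fusion result as from the corresponding ensemble function; for
#'   `"majority"`, scores are converted to votes at 0.5 first and the fused
#'   vote is rescaled to \[0, 1\] in `scores01` for rank-based evaluation.
#' @export
fuseScores <- function(scores, strategy = c("mean", "majority", "topk"),
                       K = NULL) {
  strategy <- match.arg(strategy)
  out <- switch(strategy,
    mean = meanEnsemble(scores),
    majority = majorityVoteEnsemble(lapply(scores, scoresToVotes)),
    topk = topKEnsemble(scores, K))
  out$scores01 <- if (strategy == "majority") (out$fused + 1) / 2 else
    out$fused
  out
}
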