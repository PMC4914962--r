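# Independent brute-force oracles. These are deliberately written as plain
# loops over the definitions, sharing no code with the package internals.

# maximal number of identical aligned pairs in a global alignment with free
# gaps = longest common subsequence, by dynamic programming
oracleMaxMatches <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j] + (x[i] == y[j]), M[i, j + 1],
                             M[i + 1, j])
    }
  }
  M[n + 1, m + 1]
}

oracleIdentity <- function(a, b) {
  oracleMaxMatches(a, b) / min(nchar(a), nchar(b))
}

# literal-counting 188D oracle: compositions, adjacent group pairs and
# occurrence positions counted directly from the string
oracle188 <- function(seq, grouping = ctdGroupings()) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  aa <- aminoAcids()
  out <- numeric(0)
  for (a in aa) out <- c(out, sum(ch == a) / L)
  for (p in names(grouping)) {
    for (g in 1:3) out <- c(out, sum(ch %in% grouping[[p]][[g]]) / L)
  }
  for (p in names(grouping)) {
    gidx <- function(r) which(vapply(grouping[[p]], function(g) r %in% g,
                                     logical(1)))
    gs <- vapply(ch, gidx, integer(1))
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0
      if (L >= 2) {
        for (i in 1:(L - 1)) {
          if ((gs[i] == pr[1] && gs[i + 1] == pr[2]) ||
              (gs[i] == pr[2] && gs[i + 1] == pr[1])) cnt <- cnt + 1
        }
      }
      out <- c(out, if (L >= 2) cnt / (L - 1) else 0)
    }
  }
  for (p in names(grouping)) {
    gidx <- function(r) which(vapply(grouping[[p]], function(g) r %in% g,
                                     logical(1)))
    gs <- vapply(ch, gidx, integer(1))
    for (g in 1:3) {
      occ <- which(gs == g)
      if (!length(occ)) { out <- c(out, rep(0, 5)); next }
      n <- length(occ)
      for (frac in c(NA, 0.25, 0.5, 0.75, 1)) {
        at <- if (is.na(frac)) 1 else ceiling(frac * n)
        out <- c(out, occ[at] / L)
      }
    }
  }
  unname(out)
}

# residue-conditioned PSSM averaging, direct per-residue loop
oracle420 <- function(profile) {
  s <- 1 / (1 + exp(-profileScores(profile)))
  ch <- strsplit(profileResidues(profile), "")[[1]]
  co <- profile@columnOrder
  out <- numeric(0)
  for (j in 1:20) out <- c(out, mean(s[, j]))
  for (a in co) {
    rows <- which(ch == a)
    for (j in 1:20) {
      out <- c(out, if (length(rows)) mean(s[rows, j]) else 0)
    }
  }
  out
}

# PseAAC theta factors straight from the standardized scales
oraclePseAAC <- function(seq, lam, w) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  aa <- aminoAcids()
  H1raw <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
             H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
             P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
             W = 0.81, Y = 0.26)[aa]
  H2raw <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
             H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
             P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
             W = -3.4, Y = -2.3)[aa]
  Mraw <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
            K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
            T = 45, V = 43, W = 130, Y = 107)[aa]
  std <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  H1 <- std(H1raw); H2 <- std(H2raw); Mm <- std(Mraw)
  Theta <- function(a, b) ((H1[a] - H1[b])^2 + (H2[a] - H2[b])^2 +
                             (Mm[a] - Mm[b])^2) / 3
  theta <- numeric(lam)
  for (k in seq_len(lam)) {
    acc <- 0
    for (i in 1:(L - k)) acc <- acc + Theta(ch[i], ch[i + k])
    theta[k] <- acc / (L - k)
  }
  f <- vapply(aa, function(a) sum(ch == a) / L, numeric(1))
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

# brute-force MLkNN: enumerate each instance's neighbors and tally counts
oracleMLkNN <- function(X, Y, k, s) {
  N <- nrow(X); q <- ncol(Y)
  ids <- rownames(X)
  dists <- as.matrix(dist(X))
  nnOf <- function(i, exclude) {
    d <- dists[i, ]
    if (exclude) d[i] <- Inf
    order(d, ids)[1:k]
  }
  priors <- numeric(q)
  condPos <- matrix(0, q, k + 1)
  condNeg <- matrix(0, q, k + 1)
  for (j in 1:q) {
    priors[j] <- (s + sum(Y[, j])) / (2 * s + N)
    cPos <- rep(0, k + 1); cNeg <- rep(0, k + 1)
    for (i in 1:N) {
      c0 <- sum(Y[nnOf(i, TRUE), j])
      if (Y[i, j] == 1) cPos[c0 + 1] <- cPos[c0 + 1] + 1
      else cNeg[c0 + 1] <- cNeg[c0 + 1] + 1
    }
    condPos[j, ] <- (s + cPos) / (s * (k + 1) + sum(cPos))
    condNeg[j, ] <- (s + cNeg) / (s * (k + 1) + sum(cNeg))
  }
  posterior <- function(Xq) {
    out <- matrix(0, nrow(Xq), q)
    for (m in 1:nrow(Xq)) {
      d <- sqrt(colSums((t(X) - Xq[m, ])^2))
      nn <- order(d, ids)[1:k]
      for (j in 1:q) {
        c0 <- sum(Y[nn, j])
        num <- priors[j] * condPos[j, c0 + 1]
        den <- num + (1 - priors[j]) * condNeg[j, c0 + 1]
        out[m, j] <- num / den
      }
    }
    out
  }
  list(priors = priors, condPos = condPos, condNeg = condNeg,
       posterior = posterior)
}

# brute-force BRkNN neighbor counting
oracleBRkNN <- function(X, Y, Xq, k) {
  ids <- rownames(X)
  out <- matrix(0, nrow(Xq), ncol(Y))
  for (m in 1:nrow(Xq)) {
    d <- sqrt(colSums((t(X) - Xq[m, ])^2))
    nn <- order(d, ids)[1:k]
    for (j in 1:ncol(Y)) out[m, j] <- sum(Y[nn, j]) / k
  }
  out
}

# independently coded double-loop ranking average precision
oracleAP <- function(scores, truth) {
  total <- 0; used <- 0
  for (i in 1:nrow(scores)) {
    trueIdx <- which(truth[i, ] == 1)
    if (!length(trueIdx)) next
    used <- used + 1
    acc <- 0
    for (l in trueIdx) {
      rl <- 0
      for (j in 1:ncol(scores)) if (scores[i, j] >= scores[i, l]) rl <- rl + 1
      above <- 0
      for (l2 in trueIdx) if (scores[i, l2] >= scores[i, l]) above <- above + 1
      acc <- acc + above / rl
    }
    total <- total + acc / length(trueIdx)
  }
  total / used
}

# hand-rolled IRLS for binomial logistic regression
oracleIRLS <- function(X, y, iters = 60) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (it in 1:iters) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wd <- mu * (1 - mu)
    Wd[Wd < 1e-10] <- 1e-10
    z <- eta + (y - mu) / Wd
    fit <- tryCatch(
      solve(t(X1) %*% (Wd * X1) + diag(1e-10, ncol(X1)),
            t(X1) %*% (Wd * z)),
      error = function(e) beta)
    if (max(abs(fit - beta)) < 1e-12) { beta <- fit; break }
    beta <- fit
  }
  function(Xq) as.vector(1 / (1 + exp(-cbind(1, Xq) %*% beta)))
}

# random sequence / fixture builders --------------------------------------

randomSequence <- function(len, alphabet = aminoAcids()) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

mutateSequence <- function(seq, rate, alphabet = aminoAcids()) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), ceiling(rate * length(ch)))
  ch[idx] <- sample(alphabet, length(idx), replace = TRUE)
  paste(ch, collapse = "")
}

# 30 sequences: 10 random templates plus 20 point-mutated near-copies with
# identity >= 0.8 to their template
redundancyFixture <- function(seed = 5) {
  set.seed(seed)
  templates <- vapply(1:10, function(i) randomSequence(sample(60:120, 1)),
                      character(1))
  copies <- vapply(rep(1:10, 2), function(i)
    mutateSequence(templates[i], rate = 0.15), character(1))
  seqs <- c(templates, copies)
  MultiLabelDataset(ids = sprintf("fx%02d", seq_along(seqs)),
                    sequences = seqs,
                    labels = as.list(rep("Loc", length(seqs))),
                    vocabulary = "Loc")
}

randomScoreMatrices <- function(P, n, q) {
  lapply(seq_len(P), function(p) matrix(runif(n * q), n, q))
}

smallDataset <- function(n = 12, q = 3, seed = 3, effectSize = 3) {
  generateDataset(generatorConfig(n = n, q = q, effectSize = effectSize,
                                  seed = seed))$dataset
}
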