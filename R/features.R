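# Physicochemical groupings and amino-acid property scales used by the
# composition/transition/distribution (CTD) and PseAAC extractors.

#' Standard CTD physicochemical groupings
#'
#' Eight physicochemical properties, each partitioning the 20 standard amino
#' acids into three disjoint, covering groups — the classic groupings used
#' for composition/transition/distribution sequence descriptors
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility,
#' surface tension). The groupings can be overridden by passing a modified
#' copy to [extract188D()], as long as every property keeps 3 non-empty
#' groups that cover all 20 residues.
#'
#' @return Named list of 8 properties; each a list of 3 character vectors.
#' @export
ctdGroupings <- function() {
  list(
    hydrophobicity = list(
      c("R", "K", "E", "D", "Q", "N"),
      c("G", "A", "S", "T", "P", "H", "Y"),
      c("C", "L", "V", "I", "M", "F", "W")),
    vdwVolume = list(
      c("G", "A", "S", "C", "T", "P", "D"),
      c("N", "V", "E", "Q", "I", "L"),
      c("M", "H", "K", "F", "R", "Y", "W")),
    polarity = list(
      c("L", "I", "F", "W", "C", "M", "V", "Y"),
      c("P", "A", "T", "G", "S"),
      c("H", "Q", "R", "K", "N", "E", "D")),
    polarizability = list(
      c("G", "A", "S", "D", "T"),
      c("C", "P", "N", "V", "E", "Q", "I", "L"),
      c("K", "M", "H", "F", "R", "Y", "W")),
    charge = list(
      c("K", "R"),
      c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S", "T",
        "W", "Y", "V"),
      c("D", "E")),
    secondaryStructure = list(
      c("E", "A", "L", "M", "Q", "K", "R", "H"),
      c("V", "I", "Y", "C", "W", "F", "T"),
      c("G", "N", "P", "S", "D")),
    solventAccessibility = list(
      c("A", "L", "F", "C", "G", "I", "V", "W"),
      c("R", "K", "Q", "E", "N", "D"),
      c("M", "S", "P", "T", "H", "Y")),
    surfaceTension = list(
      c("G", "Q", "D", "N", "A", "H", "R"),
      c("K", "T", "S", "E", "C"),
      c("I", "L", "M", "F", "P", "W", "Y", "V"))
  )
}

validateGrouping <- function(grouping) {
  if (length(grouping) != 8)
    stop("grouping must define exactly 8 properties")
  for (p in names(grouping)) {
    g <- grouping[[p]]
    if (length(g) != 3 || any(lengths(g) == 0))
      stop("property '", p, "' must have 3 non-empty groups")
    all20 <- sort(unlist(g))
    if (!identical(all20, aminoAcids()))
      stop("property '", p, "' groups must partition the 20 amino acids")
  }
  invisible(grouping)
}

# classic PseAAC property scales (raw, before standardization)
pseaacScales <- function() {
  aa <- aminoAcids()
  hydrophobicity <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                      G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                      M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                      S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  hydrophilicity <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                      G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                      M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                      S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  sideChainMass <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
                     H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
                     P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
                     W = 130, Y = 107)
  rbind(hydrophobicity = hydrophobicity[aa],
        hydrophilicity = hydrophilicity[aa],
        sideChainMass = sideChainMass[aa])
}

#' 188-dimensional composition and physicochemical feature vector
#'
#' Concatenates, in order: (1) the 20 amino-acid composition frequencies;
#' (2) 24 group-content values (8 properties x 3 groups: fraction of
#' residues in each group); (3) 24 transition ("bivalent") frequencies — for
#' each property and each unordered group pair, the number of adjacent
#' residue pairs whose groups form that pair (either order) divided by L-1;
#' (4) 120 distribution descriptors — for each property, group and
#' checkpoint in \{first, 25\%, 50\%, 75\%, 100\% of the group's
#' occurrences\}, the 1-based position of that occurrence divided by L (0
#' when the group is absent; fractional occurrence indices use the ceiling).
#'
#' @param seq amino-acid sequence (normalized internally).
#' @param grouping physicochemical grouping, default [ctdGroupings()].
#' @return Named numeric vector of length 188.
#' @export
extract188D <- function(seq, grouping = ctdGroupings()) {
  validateGrouping(grouping)
  seq <- normalizeResidues(seq)
  L <- nchar(seq)
  if (L == 0) stop("sequence is empty after residue normalization")
  chars <- strsplit(seq, "")[[1]]
  aa <- aminoAcids()
  aac <- tabulate(match(chars, aa), nbins = 20) / L
  names(aac) <- paste0("aac.", aa)

  comp <- numeric(0); trans <- numeric(0); distr <- numeric(0)
  pairIdx <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in names(grouping)) {
    groupOf <- integer(20)
    for (g in 1:3) groupOf[match(grouping[[p]][[g]], aa)] <- g
    gseq <- groupOf[match(chars, aa)]
    cnt <- tabulate(gseq, nbins = 3) / L
    names(cnt) <- paste0("comp.", p, ".g", 1:3)
    comp <- c(comp, cnt)

    tr <- numeric(3)
    if (L >= 2) {
      a <- gseq[-L]; b <- gseq[-1]
      for (k in 1:3) {
        pr <- pairIdx[[k]]
        tr[k] <- sum((a == pr[1] & b == pr[2]) | (a == pr[2] & b == pr[1])) /
          (L - 1)
      }
    }
    names(tr) <- paste0("trans.", p, ".g", vapply(pairIdx, paste,
                                                  character(1), collapse = "g"))
    trans <- c(trans, tr)

    for (g in 1:3) {
      pos <- which(gseq == g)
      d <- numeric(5)
      if (length(pos)) {
        n <- length(pos)
        idx <- c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
        d <- pos[idx] / L
      }
      names(d) <- paste0("distr.", p, ".g", g, ".",
                         c("first", "p25", "p50", "p75", "p100"))
      distr <- c(distr, d)
    }
  }
  c(aac, comp, trans, distr)
}

#' 20-dimensional PSSM feature vector
#'
#' Each raw log-odds score x is mapped through the logistic function
#' 1/(1+exp(-x)) and the 20 components are the per-column means over the L
#' positions (so an all-zero profile gives 0.5 everywhere). Set
#' `normalize = "raw"` to average the raw scores instead.
#'
#' @param profile a [PSSMProfile-class].
#' @param normalize `"logistic"` (default) or `"raw"`.
#' @return Named numeric vector of length 20 (profile column order).
#' @export
extractPSSM20 <- function(profile, normalize = c("logistic", "raw")) {
  normalize <- match.arg(normalize)
  if (length(profile) < 1) stop("profile must have at least one position")
  s <- profileScores(profile)
  if (normalize == "logistic") s <- plogis(s)
  setNames(colMeans(s), paste0("pssm.", profile@columnOrder))
}

#' 420-dimensional PSSM feature vector
#'
#' Concatenation of the 20 components of [extractPSSM20()] with 400
#' residue-conditioned components: for each amino-acid type a and profile
#' column j, the mean of the (normalized) scores over the positions whose
#' query residue is a, or 0 when a does not occur in the sequence.
#'
#' @inheritParams extractPSSM20
#' @return Named numeric vector of length 420.
#' @export
extractPSSM420 <- function(profile, normalize = c("logistic", "raw")) {
  normalize <- match.arg(normalize)
  base <- extractPSSM20(profile, normalize)
  s <- profileScores(profile)
  if (normalize == "logistic") s <- plogis(s)
  chars <- strsplit(profileResidues(profile), "")[[1]]
  co <- profile@columnOrder
  cond <- matrix(0, nrow = 20, ncol = 20,
                 dimnames = list(co, co))
  for (a in co) {
    at <- chars == a
    if (any(at)) cond[a, ] <- colMeans(s[at, , drop = FALSE])
  }
  condVec <- as.vector(t(cond))
  names(condVec) <- paste0("pssm.", rep(co, each = 20), ".", rep(co, 20))
  c(base, condVec)
}

#' Type-1 pseudo-amino acid composition (PseAAC)
#'
#' The first 20 components are the amino-acid frequencies and the next
#' `lam` components are sequence-order correlation factors, both normalized
#' so the vector sums to 1: component a = f_a / (sum f + w * sum theta) and
#' component 20+k = w * theta_k / (sum f + w * sum theta). theta_k is the
#' mean over residue pairs at distance k of the mean squared difference of
#' three property scales (hydrophobicity, hydrophilicity, side-chain mass),
#' each z-standardized over the 20 residues.
#'
#' @param seq amino-acid sequence; its normalized length must exceed `lam`.
#' @param lam number of correlation tiers (non-negative integer), default 4.
#' @param w weight of the sequence-order terms in (0, 1\], default 0.05.
#' @return Named numeric vector of length 20 + lam summing to 1.
#' @export
extractPseAAC <- function(seq, lam = 4, w = 0.05) {
  stopifnot(lam >= 0, w > 0, w <= 1)
  seq <- normalizeResidues(seq)
  L <- nchar(seq)
  if (L <= lam)
    stop("sequence length after normalization (", L,
         ") must exceed lam (", lam, ")")
  chars <- strsplit(seq, "")[[1]]
  aa <- aminoAcids()
  f <- tabulate(match(chars, aa), nbins = 20) / L

  sc <- pseaacScales()
  sc <- t(apply(sc, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  colnames(sc) <- aa
  theta <- numeric(lam)
  if (lam > 0) {
    idx <- match(chars, aa)
    for (k in seq_len(lam)) {
      i <- seq_len(L - k)
      d2 <- (sc[, idx[i], drop = FALSE] - sc[, idx[i + k], drop = FALSE])^2
      theta[k] <- mean(colMeans(d2))
    }
  }
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, if (lam > 0) w * theta / denom)
  names(out) <- c(paste0("pseaac.", aa),
                  if (lam > 0) paste0("pseaac.theta", seq_len(lam)))
  out
}

#' Featurize every record of a dataset
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param extractor one of `"188d"`, `"pssm20"`, `"pssm420"`, `"pseaac"`.
#' @param pssms named list id -> [PSSMProfile-class]; required by the PSSM
#'   extractors. Each profile's residues must equal the record's sequence.
#' @param lam,w PseAAC parameters (see [extractPseAAC()]).
#' @param normalize PSSM score normalization (see [extractPSSM20()]).
#' @param grouping CTD grouping (see [extract188D()]).
#' @return Numeric N x d matrix, row order = record order, rownames = ids,
#'   with attribute `extractor`.
#' @export
featurizeDataset <- function(dataset,
                             extractor = c("188d", "pssm20", "pssm420",
                                           "pseaac"),
                             pssms = NULL, lam = 4, w = 0.05,
                             normalize = "logistic",
                             grouping = ctdGroupings()) {
  extractor <- match.arg(extractor)
  ids <- proteinIds(dataset)
  seqs <- unname(as.character(sequences(dataset)))
  needsPssm <- extractor %in% c("pssm20", "pssm420")
  if (needsPssm) {
    for (id in ids) {
      pf <- pssms[[id]]
      if (is.null(pf))
        stop("no PSSM profile for id '", id, "'")
      if (!identical(profileResidues(pf), seqs[match(id, ids)]))
        stop("PSSM residues disagree with sequence for id '", id, "'")
    }
  }
  rows <- lapply(seq_along(ids), function(i) {
    switch(extractor,
      "188d" = extract188D(seqs[i], grouping),
      "pssm20" = extractPSSM20(pssms[[ids[i]]], normalize),
      "pssm420" = extractPSSM420(pssms[[ids[i]]], normalize),
      "pseaac" = extractPseAAC(seqs[i], lam, w))
  })
  d <- switch(extractor, "188d" = 188, "pssm20" = 20, "pssm420" = 420,
              "pseaac" = 20 + lam)
  X <- matrix(0, nrow = length(ids), ncol = d)
  if (length(rows)) {
    X <- do.call(rbind, rows)
  } else {
    colnames(X) <- NULL
  }
  rownames(X) <- ids
  if (any(!is.finite(X)))
    stop("non-finite feature values produced by extractor ", extractor)
  attr(X, "extractor") <- extractor
  X
}
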