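# Synthetic multi-label protein data with controllable label-composition
# signal, emulating an integrated localization training set at desk scale.

# approximate background amino-acid frequencies of a large curated protein
# database, in canonical alphabet order
backgroundComposition <- function() {
  bg <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
          H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
          P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.86,
          W = 1.10, Y = 2.92)
  bg / sum(bg)
}

# deterministic stream-splitting: each named stream gets its own sub-seed
# derived from the master seed, so reproducibility holds regardless of call
# order between streams
splitSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435 + 11) %% 2147483647)
}

#' Configuration for the synthetic dataset generator
#'
#' @param n number of proteins.
#' @param q number of labels.
#' @param labelPrior marginal probability of each label (length q or 1,
#'   values in (0, 1)); default 0.3.
#' @param cooccurrence q x q symmetric log-odds matrix of pairwise label
#'   dependence (0 = independent labels).
#' @param effectSize non-negative scale of the label-specific composition
#'   bias; 0 removes all sequence signal.
#' @param lengthRange integer (min, max) residue counts, min >= 10.
#' @param conservation PSSM sharpness in \[0, 1\] (1 = noiseless profile).
#' @param seed master RNG seed; all generator randomness derives from it.
#' @return Named list of validated generator settings.
#' @export
generatorConfig <- function(n = 200, q = 5, labelPrior = 0.3,
                            cooccurrence = NULL, effectSize = 2,
                            lengthRange = c(50, 200), conservation = 0.9,
                            seed = 1) {
  labelPrior <- rep_len(labelPrior, q)
  stopifnot(n >= 1, q >= 1, all(labelPrior > 0), all(labelPrior < 1),
            effectSize >= 0, length(lengthRange) == 2,
            lengthRange[1] >= 10, lengthRange[2] >= lengthRange[1],
            conservation >= 0, conservation <= 1)
  if (is.null(cooccurrence)) cooccurrence <- matrix(0, q, q)
  cooccurrence <- as.matrix(cooccurrence)
  stopifnot(all(dim(cooccurrence) == q),
            isTRUE(all.equal(cooccurrence, t(cooccurrence))))
  list(n = n, q = q, labelPrior = labelPrior, cooccurrence = cooccurrence,
       effectSize = effectSize, lengthRange = lengthRange,
       conservation = conservation, seed = seed)
}

# Gibbs sampling from the pairwise (Ising-like) label model; exact for a
# zero interaction matrix
sampleLabelMatrix <- function(n, alpha, J, sweeps = 25, maxTries = 50) {
  q <- length(alpha)
  Y <- matrix(0L, n, q)
  for (i in seq_len(n)) {
    for (try in seq_len(maxTries)) {
      y <- rbinom(q, 1, plogis(alpha))
      for (sw in seq_len(sweeps)) {
        for (j in seq_len(q)) {
          eta <- alpha[j] + sum(J[j, -j] * y[-j])
          y[j] <- rbinom(1, 1, plogis(eta))
        }
      }
      if (sum(y) >= 1) break
    }
    if (sum(y) == 0) y[which.max(alpha)] <- 1L
    Y[i, ] <- y
  }
  Y
}

#' Generate a synthetic multi-label protein dataset
#'
#' Label sets are drawn from a pairwise (Ising-like) model by Gibbs
#' sampling, resampling any empty set. Each label owns a fixed composition
#' direction: a Dirichlet draw, log-transformed, centered and scaled to unit
#' Euclidean norm. A protein's residue distribution is
#' softmax(log(background) + effectSize * mean of its labels' directions),
#' residues are drawn i.i.d. from it and lengths uniformly from
#' `lengthRange`. The true directions are returned for parameter-recovery
#' tests.
#'
#' @param config a [generatorConfig()] list.
#' @return list with `dataset` (a [MultiLabelDataset-class]) and
#'   `directions` (q x 20 matrix of the true composition directions).
#' @export
generateDataset <- function(config = generatorConfig()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  q <- config$q; n <- config$n
  vocab <- paste0("Loc", seq_len(q))
  aa <- aminoAcids()

  set.seed(splitSeed(config$seed, "labels"))
  alpha <- qlogis(config$labelPrior)
  Y <- sampleLabelMatrix(n, alpha, config$cooccurrence)
  colnames(Y) <- vocab

  set.seed(splitSeed(config$seed, "directions"))
  directions <- t(vapply(seq_len(q), function(l) {
    g <- log(rgamma(20, shape = 1))
    g <- g - mean(g)
    g / sqrt(sum(g^2))
  }, numeric(20)))
  dimnames(directions) <- list(vocab, aa)

  set.seed(splitSeed(config$seed, "sequences"))
  bg <- log(backgroundComposition())
  lens <- sample(config$lengthRange[1]:config$lengthRange[2], n,
                 replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    dir <- colMeans(directions[Y[i, ] == 1, , drop = FALSE])
    logits <- bg + config$effectSize * dir
    p <- exp(logits - max(logits)); p <- p / sum(p)
    paste(sample(aa, lens[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))

  ds <- MultiLabelDataset(ids = sprintf("syn%05d", seq_len(n)),
                          sequences = seqs, labels = Y,
                          vocabulary = vocab, sources = "synthetic")
  list(dataset = ds, directions = directions)
}

#' Generate a synthetic PSSM profile for one protein
#'
#' Emulates the profile a homology search would produce: at conservation 1
#' every position's highest log-odds score sits at the true residue (+7,
#' with -2 elsewhere); at conservation 0 the rows are pure integer noise in
#' \[-4, 4\], independent of the sequence. Intermediate values mix the two
#' linearly before rounding to integers.
#'
#' @param sequence amino-acid sequence string (or a single-row record from
#'   [readFasta()]).
#' @param conservation profile sharpness in \[0, 1\].
#' @param seed RNG seed for the noise component.
#' @return A [PSSMProfile-class] whose residues equal the input sequence.
#' @export
generatePSSM <- function(sequence, conservation = 0.9, seed = 1) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  sequence <- normalizeResidues(sequence)
  stopifnot(conservation >= 0, conservation <= 1, nchar(sequence) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  co <- pssmColumnOrder()
  signal <- matrix(-2, L, 20, dimnames = list(NULL, co))
  signal[cbind(seq_len(L), match(chars, co))] <- 7
  noise <- matrix(sample(-4:4, L * 20, replace = TRUE), L, 20)
  scores <- round(conservation * signal + (1 - conservation) * noise)
  PSSMProfile(residues = sequence, scores = scores, columnOrder = co)
}

#' Generate PSSM profiles for every record of a dataset
#'
#' Each record's noise seed is derived deterministically from `seed` and the
#' record index.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param conservation profile sharpness in \[0, 1\].
#' @param seed master seed.
#' @return Named list id -> [PSSMProfile-class].
#' @export
generatePSSMSet <- function(dataset, conservation = 0.9, seed = 1) {
  ids <- proteinIds(dataset)
  seqs <- as.character(sequences(dataset))
  setNames(lapply(seq_along(ids), function(i)
    generatePSSM(seqs[i], conservation,
                 splitSeed(seed, paste0("pssm", i)))), ids)
}
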