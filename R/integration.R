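#' Pairwise sequence identity (CD-HIT convention)
#'
#' Identity between two sequences is the maximal number of identical aligned
#' residue pairs over all global alignments (match 1, mismatch 0, linear gap
#' cost 0 — i.e. the length of the longest common subsequence), divided by
#' the length of the SHORTER sequence, matching the convention of greedy
#' incremental clustering tools.
#'
#' @param a,b non-empty amino-acid sequences (character strings).
#' @return Identity fraction in \[0, 1\].
#' @export
#' @examples
#' pairwiseIdentity("ACDE", "ACDE")  # 1
#' pairwiseIdentity("AAAA", "AATA")  # 0.75
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("pairwiseIdentity requires non-empty sequences")
  mat <- diag(1, 20)
  dimnames(mat) <- list(aminoAcids(), aminoAcids())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE)
  aln / min(nchar(a), nchar(b))
}

#' Merge labelled protein sources into one multi-label dataset
#'
#' Each source contributes records (a data.frame with `id`, `sequence`,
#' `source` as from [readFasta()]), a label table (named list id -> labels,
#' as from [readLabelTable()]) and a map from the source's label names onto
#' canonical names. Identical sequences occurring in several sources are
#' collapsed to one record whose label set is the union of the mapped label
#' sets; the collapsed record keeps the id of the earliest source. The
#' canonical vocabulary is the union of mapped names in first-seen order.
#'
#' @param sources list of lists, each with elements `records`, `labels` and
#'   optionally `map` (named character vector source-name -> canonical name;
#'   identity when absent).
#' @return A [MultiLabelDataset-class].
#' @export
mergeSources <- function(sources) {
  vocab <- character()
  seqKey <- character()       # normalized sequence -> merged index
  ids <- character(); seqs <- character(); srcs <- character()
  labelSets <- list()
  for (s in seq_along(sources)) {
    src <- sources[[s]]
    recs <- src$records
    tab <- src$labels
    map <- src$map
    srcName <- if (!is.null(src$name)) src$name else
      if (nrow(recs)) recs$source[1] else paste0("source", s)
    for (i in seq_len(nrow(recs))) {
      id <- recs$id[i]
      sq <- normalizeResidues(recs$sequence[i])
      rawLabs <- tab[[id]]
      if (is.null(rawLabs) || !length(rawLabs))
        stop("source '", srcName, "': no labels for record '", id, "'")
      if (!is.null(map)) {
        unmapped <- setdiff(rawLabs, names(map))
        if (length(unmapped))
          stop("source '", srcName, "': unmapped label(s) ",
               paste(unmapped, collapse = ", "))
        labs <- unname(map[rawLabs])
      } else labs <- rawLabs
      vocab <- union(vocab, labs)
      at <- match(sq, seqKey)
      if (is.na(at)) {
        seqKey <- c(seqKey, sq)
        ids <- c(ids, id); seqs <- c(seqs, sq); srcs <- c(srcs, srcName)
        labelSets[[length(seqKey)]] <- labs
      } else {
        labelSets[[at]] <- union(labelSets[[at]], labs)
      }
    }
  }
  MultiLabelDataset(ids = ids, sequences = seqs, labels = labelSets,
                    vocabulary = vocab, sources = srcs)
}

#' Greedy longest-first redundancy reduction
#'
#' CD-HIT scheme: records are sorted by sequence length descending (ties by
#' id), scanned in order, and a record is retained iff its identity
#' ([pairwiseIdentity()]) to every already-retained record is below the
#' threshold. Retained records keep their full label sets; after reduction
#' every retained pair has identity strictly below the threshold.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @param threshold identity threshold in (0, 1\]; the headline setting for
#'   localization benchmarks is 0.4.
#' @return The reduced [MultiLabelDataset-class] (record order: longest
#'   first).
#' @export
reduceRedundancy <- function(dataset, threshold = 0.4) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(dataset) <= 1) return(dataset)
  sq <- as.character(sequences(dataset))
  ord <- order(-nchar(sq), proteinIds(dataset))
  keep <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (pairwiseIdentity(sq[i], sq[j]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  dataset[keep]
}

#' Split a dataset into single-label and multi-label subsets
#'
#' @param dataset a [MultiLabelDataset-class].
#' @return list with elements `single` (records carrying exactly one label)
#'   and `multi` (records with two or more); the two partition the input and
#'   share its vocabulary.
#' @export
splitSingleMulti <- function(dataset) {
  m <- rowSums(labelMatrix(dataset))
  list(single = dataset[m == 1], multi = dataset[m >= 2])
}

#' Locative sequence count
#'
#' A protein residing in m subcellular compartments is counted m times
#' ("locative" accounting): the count is the sum of the binary label matrix.
#'
#' @param dataset a [MultiLabelDataset-class].
#' @return Integer locative count (>= number of records, with equality iff
#'   the dataset is purely single-label).
#' @export
locativeCount <- function(dataset) {
  as.integer(sum(labelMatrix(dataset)))
}
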