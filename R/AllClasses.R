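#' @import methods
#' @importFrom stats plogis qlogis rbinom runif rgamma sd glm binomial
#'   predict setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings AAStringSet
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. This ordering
#' defines the columns of composition-type feature blocks.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Column ordering used by PSI-BLAST ASCII PSSM files
#' @return Character vector of length 20.
#' @export
pssmColumnOrder <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")
}

# ---------------------------------------------------------------------------
# MultiLabelDataset

#' MultiLabelDataset: labelled protein sequences with a binary label matrix
#'
#' Holds N protein records (id, sequence, source tag), a label vocabulary of
#' q subcellular-location names, and an N x q binary label matrix. Every
#' record carries at least one label; a protein residing in m compartments
#' contributes m "locative" sequences to the locative count.
#'
#' @slot ids character vector of unique, whitespace-free protein identifiers.
#' @slot sequences [Biostrings::AAStringSet] of the amino-acid sequences,
#'   parallel to `ids`.
#' @slot sources character vector of free-form source tags, parallel to `ids`.
#' @slot vocabulary character vector of unique label names; defines the
#'   column order of `labels`.
#' @slot labels integer matrix (N x q) with entries in {0, 1}; each row sums
#'   to at least 1.
#'
#' @aliases MultiLabelDataset-class
#' @export
setClass("MultiLabelDataset",
  slots = c(
    ids = "character",
    sequences = "AAStringSet",
    sources = "character",
    vocabulary = "character",
    labels = "matrix"
  )
)

setValidity("MultiLabelDataset", function(object) {
  n <- length(object@ids)
  msgs <- character()
  if (length(object@sequences) != n)
    msgs <- c(msgs, "ids and sequences lengths differ")
  if (length(object@sources) != n)
    msgs <- c(msgs, "ids and sources lengths differ")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "record ids must be unique")
  if (any(grepl("\\s", object@ids)))
    msgs <- c(msgs, "record ids must not contain whitespace")
  if (anyDuplicated(object@vocabulary))
    msgs <- c(msgs, "vocabulary names must be unique")
  if (!is.numeric(object@labels) && !is.integer(object@labels))
    msgs <- c(msgs, "labels must be a numeric matrix")
  if (nrow(object@labels) != n)
    msgs <- c(msgs, "labels must have one row per record")
  if (ncol(object@labels) != length(object@vocabulary))
    msgs <- c(msgs, "labels must have one column per vocabulary entry")
  if (nrow(object@labels) > 0) {
    if (!all(object@labels %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be binary")
    else if (any(rowSums(object@labels) < 1))
      msgs <- c(msgs, "every record must carry at least one label")
  }
  if (n > 0 && any(Biostrings::width(object@sequences) < 1))
    msgs <- c(msgs, "sequences must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultiLabelDataset
#'
#' @param ids character vector of unique protein identifiers.
#' @param sequences character vector or `AAStringSet` of amino-acid
#'   sequences (upper-cased; non-standard residues are normalized, see
#'   [normalizeResidues()]).
#' @param labels N x q binary matrix, or a list of character vectors of label
#'   names (one per record) from which the matrix is built.
#' @param vocabulary character vector of label names defining column order.
#'   When `labels` is a list and `vocabulary` is missing, first-seen order is
#'   used.
#' @param sources character vector of source tags (recycled if length 1).
#'
#' @return A [MultiLabelDataset-class] object.
#' @export
#' @examples
#' d <- MultiLabelDataset(
#'   ids = c("p1", "p2"),
#'   sequences = c("MKVLAAGICF", "ACDEFGHIKL"),
#'   labels = list("Nucleus", c("Nucleus", "Cytoplasm"))
#' )
#' locativeCount(d)
MultiLabelDataset <- function(ids, sequences, labels, vocabulary = NULL,
                              sources = "user") {
  ids <- as.character(ids)
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(vapply(sequences, normalizeResidues,
                                                character(1), USE.NAMES = FALSE))
  if (is.list(labels)) {
    if (is.null(vocabulary))
      vocabulary <- unique(unlist(labels, use.names = FALSE))
    labels <- labelListToMatrix(labels, vocabulary)
  } else {
    labels <- as.matrix(labels)
    storage.mode(labels) <- "integer"
    if (is.null(vocabulary)) {
      vocabulary <- colnames(labels)
      if (is.null(vocabulary))
        vocabulary <- paste0("label", seq_len(ncol(labels)))
    }
  }
  dimnames(labels) <- list(NULL, vocabulary)
  sources <- rep_len(as.character(sources), length(ids))
  names(sequences) <- ids
  new("MultiLabelDataset", ids = ids, sequences = sequences,
      sources = sources, vocabulary = vocabulary, labels = labels)
}

labelListToMatrix <- function(labelList, vocabulary) {
  m <- matrix(0L, nrow = length(labelList), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(labelList)) {
    lab <- unique(as.character(labelList[[i]]))
    miss <- setdiff(lab, vocabulary)
    if (length(miss))
      stop("label(s) not in vocabulary: ", paste(miss, collapse = ", "))
    m[i, lab] <- 1L
  }
  m
}

# ---------------------------------------------------------------------------
# PSSMProfile

#' PSSMProfile: a position-specific scoring matrix for one protein
#'
#' An L x 20 matrix of per-position log-odds scores (one row per residue of
#' the protein, one column per amino-acid type), as produced by iterative
#' profile search (e.g. `psiblast -out_ascii_pssm`).
#'
#' @slot residues single string of length L: the protein sequence the profile
#'   belongs to.
#' @slot scores numeric L x 20 matrix of log-odds scores.
#' @slot columnOrder character vector of 20 amino-acid letters giving the
#'   column ordering of `scores`.
#'
#' @aliases PSSMProfile-class
#' @export
setClass("PSSMProfile",
  slots = c(
    residues = "character",
    scores = "matrix",
    columnOrder = "character"
  )
)

setValidity("PSSMProfile", function(object) {
  msgs <- character()
  if (length(object@residues) != 1)
    msgs <- c(msgs, "residues must be a single string")
  if (ncol(object@scores) != 20)
    msgs <- c(msgs, "scores must have exactly 20 columns")
  if (nrow(object@scores) != nchar(object@residues))
    msgs <- c(msgs, "number of score rows must equal number of residues")
  if (length(object@columnOrder) != 20 ||
      anyDuplicated(object@columnOrder))
    msgs <- c(msgs, "columnOrder must be 20 distinct letters")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PSSMProfile
#'
#' @param residues single string: the protein sequence (length L).
#' @param scores numeric L x 20 matrix of log-odds scores.
#' @param columnOrder 20 amino-acid letters naming the columns; defaults to
#'   the PSI-BLAST ordering ([pssmColumnOrder()]).
#' @return A [PSSMProfile-class] object.
#' @export
PSSMProfile <- function(residues, scores, columnOrder = pssmColumnOrder()) {
  scores <- as.matrix(scores)
  colnames(scores) <- columnOrder
  new("PSSMProfile", residues = as.character(residues), scores = scores,
      columnOrder = columnOrder)
}

# ---------------------------------------------------------------------------
# EvaluationReport

#' EvaluationReport: multi-label evaluation metrics
#'
#' Carries ranking average precision (AP), Hamming loss, macro/micro
#' precision and F-measure and subset accuracy, a per-label
#' precision/recall/F table, and (for cross-validation runs) per-fold copies
#' with mean and standard deviation.
#'
#' @slot metrics named numeric vector of the aggregated metrics.
#' @slot perLabel data.frame with one row per label: tp, fp, fn, precision,
#'   recall, f.
#' @slot folds data.frame with one row per fold (empty for single-split
#'   evaluations).
#' @slot foldAssignment integer vector mapping each instance to its test
#'   fold (empty when not cross-validated).
#'
#' @aliases EvaluationReport-class
#' @export
setClass("EvaluationReport",
  slots = c(
    metrics = "numeric",
    perLabel = "data.frame",
    folds = "data.frame",
    foldAssignment = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  if (length(m) && (any(m < -1e-9) || any(m > 1 + 1e-9)))
    return("all metrics must lie in [0, 1]")
  TRUE
})
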