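#' Normalize a protein sequence to the 20-letter alphabet
#'
#' Upper-cases the sequence, maps the common ambiguity/rare codes onto their
#' closest standard residue (B->D, Z->E, J->L, U->C, O->K) and drops
#' unresolvable positions (X, *). Any other character is an error.
#'
#' @param seq single character string.
#' @return Normalized sequence string (possibly shorter than the input).
#' @export
#' @examples
#' normalizeResidues("acdBZU")  # "ACDDEC"
normalizeResidues <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- chartr("BZJUO", "DELCK", seq)
  seq <- gsub("[X*]", "", seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), aminoAcids())
  if (length(bad))
    stop("unexpected residue character(s): ", paste(bad, collapse = ", "))
  seq
}

#' Read a FASTA file of protein sequences
#'
#' Wrapped sequence lines are concatenated; the record id is the first
#' whitespace-delimited token of the header; sequences are upper-cased and
#' residue-normalized ([normalizeResidues()]). Duplicate ids are an error
#' because downstream label joins are id-keyed.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `sequence`, `source` (the file
#'   basename), one row per record, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(id = character(), sequence = character(),
                      source = character(), stringsAsFactors = FALSE))
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(set), normalizeResidues, character(1),
                 USE.NAMES = FALSE)
  if (any(nchar(seqs) == 0))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  data.frame(id = ids, sequence = seqs, source = basename(path),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns (as returned by
#'   [readFasta()]), or a [MultiLabelDataset-class].
#' @param path output file path.
#' @param width line-wrap width.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(records, path, width = 60) {
  if (is(records, "MultiLabelDataset")) {
    set <- sequences(records)
  } else {
    set <- Biostrings::AAStringSet(records$sequence)
    names(set) <- records$id
  }
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `psiblast -out_ascii_pssm` dialect: header lines, then one row
#' per position carrying the position index, the query residue and two
#' 20-column blocks (log-odds scores, then weighted observed percentages).
#' Only the first block (log-odds) is kept; the percentage block is parsed
#' and discarded. Parsing is insensitive to the amount of whitespace between
#' columns.
#'
#' @param path PSSM file path.
#' @return A [PSSMProfile-class].
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  residues <- character()
  rows <- list()
  columnOrder <- pssmColumnOrder()
  headerSeen <- FALSE
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(toks) || identical(toks, "")) next
    if (!headerSeen && all(toks %in% c(aminoAcids(), "B", "Z", "X", "*"))) {
      # column-letter header line; first 20 letters give the column order
      if (length(toks) >= 20) columnOrder <- toks[1:20]
      headerSeen <- TRUE
      next
    }
    if (grepl("^[0-9]+$", toks[1])) {
      if (length(toks) < 22)
        stop("PSSM row for position ", toks[1], " has fewer than 20 scores")
      res <- toupper(toks[2])
      if (!res %in% c(aminoAcids(), "B", "Z", "J", "U", "O", "X", "*"))
        stop("PSSM row ", toks[1], ": '", res,
             "' is not an amino-acid letter")
      sc <- suppressWarnings(as.numeric(toks[3:22]))
      if (any(is.na(sc)))
        stop("PSSM row ", toks[1], ": expected 20 numeric log-odds scores")
      residues <- c(residues, res)
      rows[[length(rows) + 1L]] <- sc
    }
    # trailer lines (K/Lambda etc.) fall through and are ignored
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), nrow = 0, ncol = 20)
  PSSMProfile(residues = normalizeResidues(paste(residues, collapse = "")),
              scores = scores, columnOrder = columnOrder)
}

#' Write a PSSMProfile in PSI-BLAST ASCII dialect
#'
#' Emits the 3 header lines, one row per position with the log-odds block and
#' a zero-filled percentage block, and a short trailer, so that files written
#' here round-trip through [readPSSM()].
#'
#' @param profile a [PSSMProfile-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writePSSM <- function(profile, path) {
  co <- profile@columnOrder
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ", paste(sprintf("%3s", co), collapse = ""),
                      " ", paste(sprintf("%3s", co), collapse = ""))), con)
  res <- strsplit(profile@residues, "")[[1]]
  for (i in seq_along(res)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(round(profile@scores[i, ]))),
                            collapse = ""),
                      " ",
                      paste(sprintf("%4d", rep(0L, 20)), collapse = "")), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Read a per-protein label table
#'
#' Accepts either format: multiple rows per id (one label each), or one row
#' per id with labels joined by `";"`. Label sets are unions over rows and
#' order-independent.
#'
#' @param path TSV file with columns `id` and `label` (header row required).
#' @param delimiter field delimiter, default tab.
#' @return Named list mapping protein id to a character vector of labels.
#' @export
readLabelTable <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(list(), character()))
  df <- read.delim(path, sep = delimiter, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0) return(setNames(list(), character()))
  if (!all(c("id", "label") %in% names(df)))
    stop("label table must have 'id' and 'label' columns")
  if (any(trimws(df$label) == ""))
    stop("empty label field for id(s): ",
         paste(df$id[trimws(df$label) == ""], collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    labs <- trimws(strsplit(df$label[i], ";", fixed = TRUE)[[1]])
    labs <- labs[labs != ""]
    out[[df$id[i]]] <- union(out[[df$id[i]]], labs)
  }
  out
}

#' Write a per-protein label table (one row per id, ";"-joined labels)
#'
#' @param assignments named list id -> character vector of labels, or a
#'   [MultiLabelDataset-class].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeLabelTable <- function(assignments, path) {
  if (is(assignments, "MultiLabelDataset")) {
    Y <- labelMatrix(assignments)
    assignments <- setNames(
      lapply(seq_len(nrow(Y)), function(i) vocabulary(assignments)[Y[i, ] == 1]),
      proteinIds(assignments))
  }
  df <- data.frame(
    id = names(assignments),
    label = vapply(assignments, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table
#'
#' One row per protein: id, ";"-joined predicted label names, then one score
#' column per label (6 decimal places), in vocabulary order.
#'
#' @param path output TSV path.
#' @param ids character vector of protein ids.
#' @param vocab label vocabulary (column order).
#' @param scores N x q numeric score matrix.
#' @param bipartition N x q binary matrix of hard predictions.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(path, ids, vocab, scores, bipartition) {
  scores <- as.matrix(scores)
  bipartition <- as.matrix(bipartition)
  if (nrow(scores) != length(ids) || ncol(scores) != length(vocab) ||
      !all(dim(scores) == dim(bipartition)))
    stop("shape mismatch between ids, vocabulary, scores and bipartition")
  predicted <- vapply(seq_along(ids), function(i)
    paste(vocab[bipartition[i, ] == 1], collapse = ";"), character(1))
  if (!length(ids)) predicted <- character(0)
  df <- data.frame(id = ids, predicted = predicted, stringsAsFactors = FALSE)
  for (j in seq_along(vocab))
    df[[paste0("score.", vocab[j])]] <- sprintf("%.6f", scores[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [writePredictions()]
#'
#' @param path TSV path.
#' @return list with `ids`, `vocabulary`, `scores` (numeric matrix) and
#'   `bipartition` (reconstructed from the predicted-label column).
#' @export
readPredictions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  vocab <- sub("^score\\.", "", grep("^score\\.", names(df), value = TRUE))
  scores <- as.matrix(vapply(paste0("score.", vocab),
                             function(cn) as.numeric(df[[cn]]),
                             numeric(nrow(df))))
  if (nrow(df) == 0)
    scores <- matrix(numeric(), 0, length(vocab))
  dimnames(scores) <- list(NULL, vocab)
  bip <- matrix(0L, nrow(df), length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(nrow(df))) {
    labs <- strsplit(df$predicted[i], ";", fixed = TRUE)[[1]]
    bip[i, labs[labs != ""]] <- 1L
  }
  list(ids = df$id, vocabulary = vocab, scores = scores, bipartition = bip)
}
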