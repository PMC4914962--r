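#' @describeIn MultiLabelDataset-class number of protein records
#' @param x,object a `MultiLabelDataset`
#' @export
setMethod("length", "MultiLabelDataset", function(x) length(x@ids))

#' Accessors for MultiLabelDataset
#'
#' `proteinIds`, `sequences`, `sourceTags`, `vocabulary` and `labelMatrix`
#' read the corresponding slots; `nLabels` returns the vocabulary size q.
#'
#' @param x a [MultiLabelDataset-class].
#' @return The slot contents (see Details of each generic).
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname dataset-accessors
#' @export
setMethod("proteinIds", "MultiLabelDataset", function(x) x@ids)

#' @rdname dataset-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname dataset-accessors
#' @export
setMethod("sequences", "MultiLabelDataset", function(x) x@sequences)

#' @rdname dataset-accessors
#' @export
setGeneric("sourceTags", function(x) standardGeneric("sourceTags"))
#' @rdname dataset-accessors
#' @export
setMethod("sourceTags", "MultiLabelDataset", function(x) x@sources)

#' @rdname dataset-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname dataset-accessors
#' @export
setMethod("vocabulary", "MultiLabelDataset", function(x) x@vocabulary)

#' @rdname dataset-accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname dataset-accessors
#' @export
setMethod("labelMatrix", "MultiLabelDataset", function(x) x@labels)

#' @rdname dataset-accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @rdname dataset-accessors
#' @export
setMethod("nLabels", "MultiLabelDataset", function(x) length(x@vocabulary))

#' Subset a MultiLabelDataset by record
#'
#' Keeps the shared vocabulary (columns) untouched so that subsets of one
#' dataset remain comparable.
#'
#' @param x a [MultiLabelDataset-class].
#' @param i integer or logical index over records.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MultiLabelDataset", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_along(x@ids)[i]
  MultiLabelDataset(
    ids = x@ids[idx],
    sequences = x@sequences[idx],
    labels = x@labels[idx, , drop = FALSE],
    vocabulary = x@vocabulary,
    sources = x@sources[idx]
  )
})

setMethod("show", "MultiLabelDataset", function(object) {
  n <- length(object@ids)
  q <- length(object@vocabulary)
  cat("MultiLabelDataset with", n, "proteins and", q, "labels\n")
  if (n > 0) {
    cat("  locative count:", sum(object@labels), "\n")
    cat("  multi-label records:", sum(rowSums(object@labels) >= 2), "\n")
    cat("  sequence lengths:", min(Biostrings::width(object@sequences)), "-",
        max(Biostrings::width(object@sequences)), "\n")
  }
  cat("  vocabulary:", paste(head(object@vocabulary, 6), collapse = ", "),
      if (q > 6) "..." else "", "\n")
})

#' @describeIn PSSMProfile-class profile length (number of positions)
#' @param x,object a `PSSMProfile`
#' @export
setMethod("length", "PSSMProfile", function(x) nchar(x@residues))

#' Accessors for PSSMProfile
#' @param x a [PSSMProfile-class].
#' @name pssm-accessors
NULL

#' @rdname pssm-accessors
#' @export
setGeneric("profileResidues", function(x) standardGeneric("profileResidues"))
#' @rdname pssm-accessors
#' @export
setMethod("profileResidues", "PSSMProfile", function(x) x@residues)

#' @rdname pssm-accessors
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))
#' @rdname pssm-accessors
#' @export
setMethod("profileScores", "PSSMProfile", function(x) x@scores)

setMethod("show", "PSSMProfile", function(object) {
  cat("PSSMProfile of length", nchar(object@residues), "\n")
  cat("  residues:", substr(object@residues, 1, 40),
      if (nchar(object@residues) > 40) "..." else "", "\n")
  cat("  score range:", min(object@scores), "to", max(object@scores), "\n")
})

#' Accessors for EvaluationReport
#'
#' `reportMetrics` returns the named vector of aggregated metrics;
#' `foldMetrics` the per-fold table; `perLabelMetrics` the per-label
#' precision/recall/F table.
#'
#' @param x an [EvaluationReport-class].
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname report-accessors
#' @export
setMethod("reportMetrics", "EvaluationReport", function(x) x@metrics)

#' @rdname report-accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))
#' @rdname report-accessors
#' @export
setMethod("foldMetrics", "EvaluationReport", function(x) x@folds)

#' @rdname report-accessors
#' @export
setGeneric("perLabelMetrics", function(x) standardGeneric("perLabelMetrics"))
#' @rdname report-accessors
#' @export
setMethod("perLabelMetrics", "EvaluationReport", function(x) x@perLabel)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  m <- object@metrics
  for (nm in names(m))
    cat(sprintf("  %-16s %.4f\n", nm, m[[nm]]))
  if (nrow(object@folds)) {
    cat(sprintf("  (%d folds; AP mean %.4f, sd %.4f)\n",
                nrow(object@folds), mean(object@folds$ap),
                stats::sd(object@folds$ap)))
  }
})
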