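## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @export
setGeneric("pairingIds", function(x) standardGeneric("pairingIds"))
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))
#' @export
setGeneric("poolGenes", function(x) standardGeneric("poolGenes"))
#' @export
setGeneric("poolStats", function(x) standardGeneric("poolStats"))
#' @export
setGeneric("poolZScores", function(x) standardGeneric("poolZScores"))
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @export
setGeneric("networkCondition", function(x) standardGeneric("networkCondition"))
#' @export
setGeneric("centralities", function(x) standardGeneric("centralities"))
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
#' @export
setGeneric("diceGenes", function(x) standardGeneric("diceGenes"))

#' Accessors for dicenet classes
#'
#' \code{exprMatrix} returns the expression assay; \code{sampleConditions}
#' the per-sample condition factor; \code{conditionLabels} the two labels
#' (first = reference "A", second = "B"); \code{pairingIds} the pairing
#' vector or \code{NULL}. \code{interactions} and \code{scoreThreshold}
#' expose the scaffold edge table and its confidence cutoff.
#' \code{poolGenes}, \code{poolStats} and \code{poolZScores} expose the
#' candidate pool; \code{networkNodes}, \code{networkEdges} and
#' \code{networkCondition} a condition network; \code{centralities} the
#' centrality table; \code{rankingTable} the ensemble ranking rows;
#' \code{diceGenes} the final gene-set table (or, applied to an
#' \code{EnsembleRanking}, its surviving rows).
#'
#' @param x an object of the documented class.
#' @return See description; tables are plain \code{data.frame}s.
#' @name accessors
#' @aliases exprMatrix sampleConditions conditionLabels pairingIds
#'   interactions scoreThreshold poolGenes poolStats poolZScores
#'   networkNodes networkEdges networkCondition centralities rankingTable
#'   diceGenes
NULL

#' @rdname accessors
#' @export
setMethod("exprMatrix", "DiceExperiment",
          function(x) SummarizedExperiment::assay(x))
#' @rdname accessors
#' @export
setMethod("sampleConditions", "DiceExperiment", function(x) {
  cond <- SummarizedExperiment::colData(x)$condition
  factor(cond, levels = unique(as.character(cond)))
})
#' @rdname accessors
#' @export
setMethod("conditionLabels", "DiceExperiment",
          function(x) levels(sampleConditions(x)))
#' @rdname accessors
#' @export
setMethod("pairingIds", "DiceExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"pairing" %in% colnames(cd)) return(NULL)
  p <- cd$pairing
  if (all(is.na(p))) NULL else as.character(p)
})
#' @rdname accessors
#' @export
setMethod("interactions", "InteractionSet", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("scoreThreshold", "InteractionSet", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("poolGenes", "CandidatePool", function(x) x@stats$gene)
#' @rdname accessors
#' @export
setMethod("poolStats", "CandidatePool", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("poolZScores", "CandidatePool", function(x) x@zscores)
#' @rdname accessors
#' @export
setMethod("networkNodes", "ConditionNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "ConditionNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkCondition", "ConditionNetwork", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("centralities", "CentralityTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("rankingTable", "EnsembleRanking", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("diceGenes", "DiceGeneSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("diceGenes", "EnsembleRanking",
          function(x) x@table[x@table$passed_filter, , drop = FALSE])

setMethod("show", "DiceExperiment", function(object) {
  cond <- sampleConditions(object)
  cat("DiceExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", levels(cond), as.integer(table(cond))),
            collapse = ", "),
      if (is.null(pairingIds(object))) "[unpaired]\n" else "[paired]\n")
})

setMethod("show", "InteractionSet", function(object) {
  cat("InteractionSet:", nrow(object@edges), "edges among",
      length(unique(c(object@edges$gene1, object@edges$gene2))),
      "genes (score >=", object@threshold, ")\n")
})

setMethod("show", "CandidatePool", function(object) {
  d <- table(object@stats$direction)
  cat("CandidatePool:", nrow(object@stats), "candidate genes (",
      paste(sprintf("%s=%d", names(d), as.integer(d)), collapse = ", "),
      ")\n  cutoffs:", object@cutoffs$statField, "<", object@cutoffs$statCut,
      if (is.null(object@cutoffs$lfcCut)) "" else
        paste(", |log2FC| >", object@cutoffs$lfcCut), "\n")
})

setMethod("show", "ConditionNetwork", function(object) {
  cat("ConditionNetwork [", object@condition, "]: ",
      length(object@nodes), " nodes, ", nrow(object@edges), " edges\n",
      sep = "")
})

setMethod("show", "CentralityTable", function(object) {
  cat("CentralityTable:", nrow(object@table), "genes; conditions A=",
      object@conditions[1L], ", B=", object@conditions[2L], "\n")
})

setMethod("show", "EnsembleRanking", function(object) {
  cat("EnsembleRanking:", nrow(object@table), "genes ranked,",
      sum(object@table$passed_filter), "passed the", object@filterMode,
      "centrality-mean filter\n")
})

setMethod("show", "DiceGeneSet", function(object) {
  d <- table(object@table$direction)
  cat("DiceGeneSet:", nrow(object@table), "genes (",
      paste(sprintf("%s=%d", names(d), as.integer(d)), collapse = ", "),
      ")\n")
  if (nrow(object@table))
    cat("  top genes:",
        paste(utils::head(object@table$gene, 5L), collapse = ", "), "\n")
})
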