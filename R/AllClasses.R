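## Central S4 containers for the pipeline. Validity methods enforce the shape
## and identifier invariants every downstream phase assumes, so failures
## surface at construction time rather than deep inside a phase.

#' DiceExperiment: two-condition expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' log-scale expression assay together with a two-group sample design
#' (\code{colData} columns \code{condition} and optionally \code{pairing}).
#' Validity requires unique gene and sample identifiers, all-finite values,
#' exactly two condition labels with at least two samples each, and -- when
#' pairing identifiers are present -- exactly one sample per condition per
#' pairing id.
#'
#' @slot ... inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{DiceExperiment}} for the constructor.
#' @export
setClass("DiceExperiment", contains = "SummarizedExperiment")

.validDiceExperiment <- function(object) {
  msg <- character(0)
  m <- SummarizedExperiment::assay(object)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "expression assay must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, sprintf("duplicate gene identifier: '%s'",
                          rownames(m)[duplicated(rownames(m))][1L]))
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, sprintf("duplicate sample identifier: '%s'",
                          colnames(m)[duplicated(colnames(m))][1L]))
  if (!is.numeric(m) || any(!is.finite(m)))
    msg <- c(msg, "expression values must all be finite numbers")
  if (nrow(m) < 2L) msg <- c(msg, "at least 2 genes are required")
  if (ncol(m) < 4L) msg <- c(msg, "at least 4 samples are required")
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else {
    cond <- as.factor(cd$condition)
    if (nlevels(cond) != 2L)
      msg <- c(msg, sprintf("exactly two condition labels required, got: %s",
                            paste(levels(cond), collapse = ", ")))
    if (any(table(cond) < 2L))
      msg <- c(msg, "each condition needs at least 2 samples")
    if ("pairing" %in% colnames(cd) && !all(is.na(cd$pairing))) {
      tab <- table(cd$pairing, cond)
      if (any(tab > 1L))
        msg <- c(msg, sprintf(
          "pairing id '%s' maps to more than one sample in one condition",
          rownames(tab)[which(apply(tab, 1L, max) > 1L)[1L]]))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("DiceExperiment", .validDiceExperiment)

#' InteractionSet: scored undirected interaction scaffold
#'
#' STRING-style gene-gene edges with integer combined scores in
#' [threshold, 1000]. Edges are stored canonically (gene1 < gene2), without
#' self-loops and without duplicates; reversed duplicates are merged at
#' construction keeping the maximum score.
#'
#' @slot edges \code{data.frame} with columns \code{gene1}, \code{gene2},
#'   \code{score}.
#' @slot threshold integer confidence cutoff the retained edges satisfy
#'   (default 400, the STRING medium-confidence convention).
#' @seealso \code{\link{InteractionSet}}, \code{\link{readInteractions}}
#' @export
setClass("InteractionSet",
         representation(edges = "data.frame", threshold = "integer"))

.validInteractionSet <- function(object) {
  e <- object@edges
  msg <- character(0)
  if (!all(c("gene1", "gene2", "score") %in% colnames(e)))
    return("edges must have columns gene1, gene2, score")
  if (nrow(e)) {
    if (any(e$gene1 == e$gene2)) msg <- c(msg, "self-loop present")
    if (any(e$gene1 > e$gene2)) msg <- c(msg, "edges not in canonical order")
    if (anyDuplicated(paste(e$gene1, e$gene2, sep = "\r")))
      msg <- c(msg, "duplicate edge present")
    if (any(e$score < object@threshold) || any(e$score > 1000))
      msg <- c(msg, sprintf("scores must lie in [%d, 1000]", object@threshold))
  }
  if (length(msg)) msg else TRUE
}
setValidity("InteractionSet", .validInteractionSet)

#' CandidatePool: relaxed-cutoff differential-expression candidates
#'
#' The Phase I product: genes passing the configured (loose) cutoffs, their
#' differential-expression statistics and up/down/flat direction labels, and
#' the z-scored expression of the retained genes across all samples.
#'
#' @slot stats \code{data.frame} with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}, \code{qvalue}, \code{direction}.
#' @slot zscores numeric matrix (pool genes x all samples), each row with
#'   mean 0 and unit variance.
#' @slot cutoffs list recording \code{statField}, \code{statCut},
#'   \code{lfcCut} used for selection.
#' @seealso \code{\link{selectCandidates}}
#' @export
setClass("CandidatePool",
         representation(stats = "data.frame", zscores = "matrix",
                        cutoffs = "list"))

.validCandidatePool <- function(object) {
  msg <- character(0)
  need <- c("gene", "log2fc", "pvalue", "qvalue", "direction")
  if (!all(need %in% colnames(object@stats)))
    return(paste("stats must have columns", paste(need, collapse = ", ")))
  if (!identical(object@stats$gene, rownames(object@zscores)))
    msg <- c(msg, "stats genes and zscore rownames disagree")
  if (nrow(object@zscores)) {
    mu <- rowMeans(object@zscores)
    s <- apply(object@zscores, 1L, stats::sd)
    if (max(abs(mu)) > 1e-9 || max(abs(s - 1)) > 1e-9)
      msg <- c(msg, "zscore rows must have mean 0 and unit sd (tol 1e-9)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CandidatePool", .validCandidatePool)

#' ConditionNetwork: correlation-weighted interaction network for one condition
#'
#' The interaction scaffold restricted to the selected genes, with each edge
#' carrying the within-condition Pearson coefficient \code{cc}, the affinity
#' \code{|cc|} and the distance \code{1 - |cc|}.
#'
#' @slot condition the condition label the weights were computed from.
#' @slot nodes character vector of gene ids (may include scaffold-isolated
#'   genes until \code{\link{pruneUnconnected}} is applied).
#' @slot edges \code{data.frame} with columns \code{gene1}, \code{gene2},
#'   \code{cc}, \code{affinity}, \code{distance}.
#' @seealso \code{\link{buildConditionNetwork}}
#' @export
setClass("ConditionNetwork",
         representation(condition = "character", nodes = "character",
                        edges = "data.frame"))

.validConditionNetwork <- function(object) {
  e <- object@edges
  msg <- character(0)
  need <- c("gene1", "gene2", "cc", "affinity", "distance")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (nrow(e)) {
    if (!all(e$gene1 %in% object@nodes) || !all(e$gene2 %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
    if (any(abs(e$cc) > 1 + 1e-12))
      msg <- c(msg, "Pearson coefficients must lie in [-1, 1]")
    if (max(abs(e$affinity + e$distance - 1)) > 1e-12)
      msg <- c(msg, "affinity + distance must equal 1 (tol 1e-12)")
    if (max(abs(e$affinity - abs(e$cc))) > 1e-12)
      msg <- c(msg, "affinity must equal |cc|")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ConditionNetwork", .validConditionNetwork)

#' CentralityTable: per-gene centralities and their absolute differences
#'
#' Betweenness (unnormalized Brandes counts on edge distances) and
#' eigenvector centrality (max-normalized, on edge affinities) for each of
#' the two conditions, plus the per-gene absolute differences driving the
#' ensemble ranking.
#'
#' @slot table \code{data.frame} with columns \code{gene},
#'   \code{betweenness_A}, \code{betweenness_B}, \code{eigen_A},
#'   \code{eigen_B}, \code{abs_delta_betweenness}, \code{abs_delta_eigen}.
#' @slot conditions length-2 character vector naming which condition label is
#'   "A" and which is "B".
#' @seealso \code{\link{centralityDeltas}}
#' @export
setClass("CentralityTable",
         representation(table = "data.frame", conditions = "character"))

.validCentralityTable <- function(object) {
  t <- object@table
  need <- c("gene", "betweenness_A", "betweenness_B", "eigen_A", "eigen_B",
            "abs_delta_betweenness", "abs_delta_eigen")
  msg <- character(0)
  if (!all(need %in% colnames(t)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (length(object@conditions) != 2L)
    msg <- c(msg, "conditions must name exactly two labels")
  if (nrow(t)) {
    if (anyDuplicated(t$gene)) msg <- c(msg, "duplicate gene in table")
    db <- abs(t$betweenness_B - t$betweenness_A)
    de <- abs(t$eigen_B - t$eigen_A)
    if (!isTRUE(all.equal(db, t$abs_delta_betweenness, tolerance = 0)) &&
        max(abs(db - t$abs_delta_betweenness)) > 0)
      msg <- c(msg, "abs_delta_betweenness must equal |B - A| exactly")
    if (max(abs(de - t$abs_delta_eigen)) > 0)
      msg <- c(msg, "abs_delta_eigen must equal |B - A| exactly")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CentralityTable", .validCentralityTable)

#' EnsembleRanking: aggregated centrality-difference ranking
#'
#' Average-tie ranks of the absolute betweenness and eigenvector differences,
#' their mean (the ensemble score), a tie-broken total final order over all
#' ranked genes, the below-mean-centrality exclusion flag, and direction
#' labels carried from the candidate pool. Survivors additionally carry a
#' re-densified \code{dice_rank} (1..n survivors); the all-gene
#' \code{final_rank} is kept as provenance.
#'
#' @slot table \code{data.frame}, one row per ranked gene; see
#'   \code{\link{writeResultsTable}} for the column contract.
#' @slot filterMode \code{"strict"} or \code{"either_measure"}.
#' @seealso \code{\link{ensembleRanking}}
#' @export
setClass("EnsembleRanking",
         representation(table = "data.frame", filterMode = "character"))

.validEnsembleRanking <- function(object) {
  t <- object@table
  need <- c("gene", "log2fc", "direction", "betweenness_A", "betweenness_B",
            "eigen_A", "eigen_B", "abs_delta_betweenness", "abs_delta_eigen",
            "rank_betweenness", "rank_eigen", "ensemble_score", "final_rank",
            "passed_filter")
  msg <- character(0)
  if (!all(need %in% colnames(t)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (nrow(t) && !identical(sort(t$final_rank), seq_len(nrow(t))))
    msg <- c(msg, "final_rank must be a permutation of 1..n")
  if (!object@filterMode %in% c("strict", "either_measure"))
    msg <- c(msg, "filterMode must be 'strict' or 'either_measure'")
  if (length(msg)) msg else TRUE
}
setValidity("EnsembleRanking", .validEnsembleRanking)

#' DiceGeneSet: the final prioritized gene set
#'
#' Genes surviving the below-mean-centrality exclusion filter, ordered by
#' their re-densified rank, annotated with direction, log2 fold change and
#' all centrality provenance columns.
#'
#' @slot table \code{data.frame}, rows sorted by \code{dice_rank}.
#' @seealso \code{\link{assembleDiceGenes}}
#' @export
setClass("DiceGeneSet", representation(table = "data.frame"))

.validDiceGeneSet <- function(object) {
  t <- object@table
  if (!"dice_rank" %in% colnames(t)) return("table must have a dice_rank column")
  if (nrow(t) && !identical(t$dice_rank, seq_len(nrow(t))))
    return("rows must be sorted by dice_rank = 1..n")
  TRUE
}
setValidity("DiceGeneSet", .validDiceGeneSet)
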