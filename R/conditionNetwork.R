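## Phase III: the static interaction scaffold is re-weighted per condition.
## Each retained edge carries the within-condition Pearson coefficient, its
## absolute value as an affinity, and 1 - |cc| as a distance-like metric for
## shortest paths. The scaffold (which pairs may be edges) is condition-
## independent; only the weights differ between the two networks.

#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson coefficient; when either vector is constant the
#' correlation is undefined and 0 is returned by convention ("no evidence of
#' co-variation"), which maps to the maximal edge distance of 1.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pearsonCC <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Build a condition-specific weighted network
#'
#' Restricts the interaction scaffold to the given genes and weights every
#' surviving edge with the Pearson correlation computed over the samples of
#' one condition only. The node set is the full gene subset; genes without
#' scaffold edges stay as isolated nodes until \code{\link{pruneUnconnected}}.
#'
#' @param genes character vector of gene ids (typically the Phase II
#'   selection).
#' @param x a \linkS4class{DiceExperiment}.
#' @param interactionSet an \linkS4class{InteractionSet}.
#' @param condition one of \code{conditionLabels(x)}.
#' @return a \linkS4class{ConditionNetwork}.
#' @export
buildConditionNetwork <- function(genes, x, interactionSet, condition) {
  stopifnot(is(x, "DiceExperiment"), is(interactionSet, "InteractionSet"))
  labs <- conditionLabels(x)
  if (!condition %in% labs)
    stop("condition '", condition, "' is not one of: ",
         paste(labs, collapse = ", "))
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(exprMatrix(x)))
  if (length(missing))
    stop("gene(s) absent from the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  e <- interactions(interactionSet)
  e <- e[e$gene1 %in% genes & e$gene2 %in% genes, , drop = FALSE]
  scaffoldGenes <- unique(c(e$gene1, e$gene2))
  if (length(scaffoldGenes) == 0L)
    stop("no interaction edge has both endpoints in the gene subset")
  cond <- sampleConditions(x)
  m <- exprMatrix(x)[genes, cond == condition, drop = FALSE]
  if (ncol(m) < 2L)
    stop("condition '", condition, "' has fewer than 2 samples")
  ## full correlation among subset genes on this condition's samples;
  ## zero-variance rows yield NA -> 0 by the pearsonCC convention
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  v <- cc[cbind(match(e$gene1, genes), match(e$gene2, genes))]
  v <- pmax(pmin(v, 1), -1)
  out <- data.frame(gene1 = e$gene1, gene2 = e$gene2, cc = v,
                    affinity = abs(v), distance = 1 - abs(v),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("ConditionNetwork", condition = condition, nodes = genes, edges = out)
}

#' Drop genes without scaffold connections from both condition networks
#'
#' The two networks share one scaffold, so a gene has degree zero in both or
#' in neither; pruning therefore yields a common node set.
#'
#' @param netA,netB the two \linkS4class{ConditionNetwork}s built from the
#'   same gene subset and interaction scaffold.
#' @return list with elements \code{A} and \code{B}, pruned networks sharing
#'   a node set.
#' @export
pruneUnconnected <- function(netA, netB) {
  stopifnot(is(netA, "ConditionNetwork"), is(netB, "ConditionNetwork"))
  if (!setequal(netA@nodes, netB@nodes))
    stop("the two networks must be built from the same gene subset")
  keyA <- paste(netA@edges$gene1, netA@edges$gene2)
  keyB <- paste(netB@edges$gene1, netB@edges$gene2)
  if (!setequal(keyA, keyB))
    stop("the two networks must share one scaffold edge set")
  connected <- unique(c(netA@edges$gene1, netA@edges$gene2))
  if (length(connected) == 0L)
    stop("no connected genes remain after pruning")
  prune <- function(net) {
    keep <- net@nodes[net@nodes %in% connected]
    new("ConditionNetwork", condition = net@condition, nodes = keep,
        edges = net@edges)
  }
  list(A = prune(netA), B = prune(netB))
}
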