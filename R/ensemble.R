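## Phase V: rank genes per centrality difference, aggregate by mean rank
## (Borda), apply the below-mean-centrality exclusion filter, emit the final
## gene set. Ranks are computed over ALL network genes, then survivors get a
## re-densified rank with the all-gene final rank kept as provenance.

#' Descending average-tie ranks
#'
#' Largest value gets rank 1; ties receive the average of the ranks they
#' span.
#'
#' @param values numeric vector, length >= 1.
#' @return numeric ranks, same length and names.
#' @examples
#' rankDescending(c(5, 3, 3, 1))  # 1, 2.5, 2.5, 4
#' @export
rankDescending <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  rank(-values, ties.method = "average")
}

#' Aggregate two per-measure rankings into a total order
#'
#' Ensemble score = mean of the two ranks; the final order sorts the score
#' ascending, breaking ties by larger absolute betweenness difference and
#' then lexicographic gene id, guaranteeing a total order.
#'
#' @param rankB,rankE average-tie ranks (same genes, same order).
#' @param genes gene ids aligned with the rank vectors.
#' @param tieBreak numeric tie-break values (larger wins), typically the
#'   absolute betweenness differences; zeros if \code{NULL}.
#' @return \code{data.frame} with columns \code{gene}, \code{ensemble_score},
#'   \code{final_rank} (in the input gene order).
#' @export
aggregateRanks <- function(rankB, rankE, genes, tieBreak = NULL) {
  if (length(rankB) != length(rankE) || length(rankB) != length(genes))
    stop("rankB, rankE and genes must have equal length")
  if (is.null(tieBreak)) tieBreak <- numeric(length(genes))
  score <- (rankB + rankE) / 2
  ord <- order(score, -tieBreak, genes)
  finalRank <- integer(length(genes))
  finalRank[ord] <- seq_along(genes)
  data.frame(gene = as.character(genes), ensemble_score = score,
             final_rank = finalRank, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Below-mean-centrality exclusion filter
#'
#' Computes the four per-measure, per-condition means (betweenness in A and
#' B, eigenvector in A and B) over all genes. In \code{"strict"} mode
#' (default) a gene passes only if all four of its values are >= the
#' corresponding mean -- i.e. it is excluded as soon as any centrality in any
#' condition falls below average. In \code{"either_measure"} mode a gene
#' passes if, in each condition, at least one of the two measures is >= its
#' mean.
#'
#' @param centralityTable a \linkS4class{CentralityTable}.
#' @param mode \code{"strict"} or \code{"either_measure"}.
#' @return logical vector aligned with the table rows.
#' @export
centralityMeanFilter <- function(centralityTable,
                                 mode = c("strict", "either_measure")) {
  stopifnot(is(centralityTable, "CentralityTable"))
  mode <- match.arg(mode)
  t <- centralities(centralityTable)
  if (nrow(t) == 0L) stop("empty centrality table")
  bA <- t$betweenness_A >= mean(t$betweenness_A)
  bB <- t$betweenness_B >= mean(t$betweenness_B)
  eA <- t$eigen_A >= mean(t$eigen_A)
  eB <- t$eigen_B >= mean(t$eigen_B)
  if (mode == "strict") bA & bB & eA & eB else (bA | eA) & (bB | eB)
}

#' Build the ensemble ranking from centrality differences
#'
#' Ranks all genes by descending |delta betweenness| and |delta eigenvector|
#' (average-tie ranks), aggregates the two rankings, applies the exclusion
#' filter, and annotates each gene with its log2 fold change and direction
#' from the candidate pool.
#'
#' @param centralityTable a \linkS4class{CentralityTable}.
#' @param pool the \linkS4class{CandidatePool} the genes came from.
#' @param filterMode passed to \code{\link{centralityMeanFilter}}.
#' @return an \linkS4class{EnsembleRanking}.
#' @export
ensembleRanking <- function(centralityTable, pool,
                            filterMode = c("strict", "either_measure")) {
  stopifnot(is(centralityTable, "CentralityTable"), is(pool, "CandidatePool"))
  filterMode <- match.arg(filterMode)
  t <- centralities(centralityTable)
  rb <- rankDescending(t$abs_delta_betweenness)
  re <- rankDescending(t$abs_delta_eigen)
  agg <- aggregateRanks(rb, re, t$gene, tieBreak = t$abs_delta_betweenness)
  ps <- poolStats(pool)
  idx <- match(t$gene, ps$gene)
  if (anyNA(idx))
    stop("centrality table gene(s) missing from the candidate pool: ",
         paste(utils::head(t$gene[is.na(idx)], 5L), collapse = ", "))
  out <- data.frame(
    gene = t$gene,
    log2fc = ps$log2fc[idx],
    direction = ps$direction[idx],
    betweenness_A = t$betweenness_A, betweenness_B = t$betweenness_B,
    eigen_A = t$eigen_A, eigen_B = t$eigen_B,
    abs_delta_betweenness = t$abs_delta_betweenness,
    abs_delta_eigen = t$abs_delta_eigen,
    rank_betweenness = rb, rank_eigen = re,
    ensemble_score = agg$ensemble_score, final_rank = agg$final_rank,
    passed_filter = centralityMeanFilter(centralityTable, filterMode),
    stringsAsFactors = FALSE, row.names = NULL)
  new("EnsembleRanking", table = out, filterMode = filterMode)
}

#' Assemble the final prioritized gene set
#'
#' Restricts the ranking to filter survivors, orders them by the all-gene
#' final rank and re-densifies it to \code{dice_rank} = 1..n survivors
#' (keeping \code{final_rank} as provenance).
#'
#' @param ranking an \linkS4class{EnsembleRanking}.
#' @param pool the \linkS4class{CandidatePool} (direction provenance check).
#' @return a \linkS4class{DiceGeneSet}.
#' @export
assembleDiceGenes <- function(ranking, pool) {
  stopifnot(is(ranking, "EnsembleRanking"), is(pool, "CandidatePool"))
  t <- diceGenes(ranking)
  if (nrow(t) == 0L)
    stop("no gene passed the centrality-mean filter; ",
         "consider filterMode = 'either_measure'")
  missing <- setdiff(t$gene, poolGenes(pool))
  if (length(missing))
    stop("surviving gene(s) missing from the candidate pool: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  t <- t[order(t$final_rank), , drop = FALSE]
  t$dice_rank <- seq_len(nrow(t))
  rownames(t) <- NULL
  new("DiceGeneSet", table = t)
}
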