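## Phase II: information-gain filter. Entropies are in bits (log2). The gain
## of a gene is the dataset class entropy minus the class entropy remaining
## after partitioning samples by the gene's discretized expression level;
## continuous values are binned first (default: 10 equal-frequency bins).

#' Class entropy of a label vector
#'
#' Shannon entropy in bits over class proportions, with 0 * log(0) := 0.
#'
#' @param classLabels vector of class labels (any atomic type), length >= 1.
#' @return list with \code{D} (entropy in bits), \code{counts} (per-class
#'   sample counts), \code{N} (total) and \code{k} (number of classes).
#' @examples
#' classEntropy(rep(c("a", "b"), 5))$D  # 1 bit
#' @export
classEntropy <- function(classLabels) {
  if (length(classLabels) == 0L) stop("empty label vector")
  counts <- table(classLabels)
  counts <- counts[counts > 0]
  p <- as.numeric(counts) / length(classLabels)
  list(D = -sum(p * log2(p)), counts = as.integer(counts),
       N = length(classLabels), k = length(counts))
}

#' Discretize a gene's expression values into bins
#'
#' \code{equal_frequency} (default) uses sample-quantile boundaries with
#' right-closed intervals; \code{equal_width} splits the observed range into
#' equal-width intervals. Identical values always share a bin. When
#' \code{nBins} exceeds the number of distinct values it is capped with a
#' warning.
#'
#' @param values finite numeric vector.
#' @param nBins integer >= 2.
#' @param strategy \code{"equal_frequency"} or \code{"equal_width"}.
#' @return integer bin index (1-based) per sample.
#' @export
discretizeGene <- function(values, nBins = 10L,
                           strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (any(!is.finite(values))) stop("values must be finite")
  if (nBins < 2L) stop("nBins must be >= 2")
  nd <- length(unique(values))
  if (nd == 1L) return(rep(1L, length(values)))
  if (nBins > nd) {
    warning("nBins (", nBins, ") exceeds the number of distinct values (",
            nd, "); capping")
    nBins <- nd
  }
  breaks <- if (strategy == "equal_frequency") {
    unique(stats::quantile(values, probs = seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  } else {
    seq(min(values), max(values), length.out = nBins + 1L)
  }
  idx <- cut(values, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  as.integer(idx)
}

#' Weighted entropy of a binned gene
#'
#' Size-weighted average of the class entropy within each expression-level
#' partition: sum_v (|N_v|/N) * Entropy(labels in bin v).
#'
#' @param bins per-sample bin indices.
#' @param classLabels per-sample class labels, same length as \code{bins}.
#' @return weighted entropy in bits.
#' @export
weightedEntropy <- function(bins, classLabels) {
  if (length(bins) != length(classLabels))
    stop("bins and classLabels must have the same length")
  N <- length(bins)
  parts <- split(seq_len(N), bins)
  sum(vapply(parts, function(i)
    length(i) / N * classEntropy(classLabels[i])$D, numeric(1L)))
}

#' Information gain of a gene for the class split
#'
#' IG = D - weightedEntropy, where D is the dataset class entropy; negative
#' rounding residue (> -1e-12) is clipped to zero.
#'
#' @inheritParams discretizeGene
#' @param classLabels per-sample class labels.
#' @return non-negative information gain in bits.
#' @export
informationGain <- function(values, classLabels, nBins = 10L,
                            strategy = c("equal_frequency", "equal_width")) {
  if (length(values) != length(classLabels))
    stop("values and classLabels must have the same length")
  bins <- discretizeGene(values, nBins, strategy)
  ig <- classEntropy(classLabels)$D - weightedEntropy(bins, classLabels)
  max(ig, 0)
}

#' Information-gain table for a candidate pool
#'
#' Scores every pool gene's discrimination power between the two conditions
#' on the z-scored candidate matrix.
#'
#' @param pool a \linkS4class{CandidatePool}.
#' @param x the \linkS4class{DiceExperiment} providing the class labels.
#' @param nBins,strategy discretization settings (see
#'   \code{\link{discretizeGene}}).
#' @return \code{data.frame} with columns \code{gene}, \code{ig},
#'   \code{kept} (the strictly-above-mean flag used by
#'   \code{\link{selectByMeanIG}}).
#' @export
informationGainTable <- function(pool, x, nBins = 10L,
                                 strategy = c("equal_frequency",
                                              "equal_width")) {
  stopifnot(is(pool, "CandidatePool"), is(x, "DiceExperiment"))
  strategy <- match.arg(strategy)
  z <- poolZScores(pool)
  labels <- as.character(sampleConditions(x))[match(colnames(z),
                                                    colnames(exprMatrix(x)))]
  ig <- suppressWarnings(apply(z, 1L, informationGain, classLabels = labels,
                               nBins = nBins, strategy = strategy))
  data.frame(gene = rownames(z), ig = as.numeric(ig),
             kept = ig > mean(ig), stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep genes whose information gain exceeds the pool mean
#'
#' Strict inequality; when every gene has the same IG the selection is empty
#' and a warning is raised (set \code{fallbackKeepAll = TRUE} to keep the
#' whole pool in that degenerate case).
#'
#' @param igTable output of \code{\link{informationGainTable}}.
#' @param fallbackKeepAll logical, default \code{FALSE}.
#' @return character vector of selected gene ids.
#' @export
selectByMeanIG <- function(igTable, fallbackKeepAll = FALSE) {
  if (nrow(igTable) == 0L) stop("empty information-gain table")
  keep <- igTable$ig > mean(igTable$ig)
  if (!any(keep)) {
    warning("all information-gain values are identical; ",
            if (fallbackKeepAll) "keeping all genes" else "selection is empty")
    if (fallbackKeepAll) keep <- rep(TRUE, nrow(igTable))
  }
  igTable$gene[keep]
}
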