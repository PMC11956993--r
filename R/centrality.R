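## Phase IV: weighted centralities per condition and their absolute
## differences. Betweenness runs on edge *distances* (1 - |cc|); eigenvector
## centrality runs on edge *affinities* (|cc|) -- an eigenvector score on
## distances would reward the weakest correlations, so the asymmetry is
## deliberate and documented in the methods vignette.

#' Weighted betweenness centrality
#'
#' Brandes' algorithm on the edge distance attribute: for each node v the sum
#' over unordered pairs (s, t), s != t != v, of the fraction of
#' minimum-distance s-t paths passing through v. Tied shortest paths share
#' credit fractionally; disconnected pairs contribute nothing; zero-distance
#' edges (|cc| = 1) are legal. Reported unnormalized by default, so values
#' are raw pair counts comparable across the two equally sized condition
#' networks; \code{normalized = TRUE} divides by (n-1)(n-2)/2.
#'
#' @param net a \linkS4class{ConditionNetwork}.
#' @param normalized logical, default \code{FALSE}.
#' @return named numeric vector over \code{networkNodes(net)}.
#' @export
weightedBetweenness <- function(net, normalized = FALSE) {
  stopifnot(is(net, "ConditionNetwork"))
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  if (any(e$distance < 0)) stop("negative edge distance")
  bc <- .brandesBetweenness(length(nodes),
                            match(e$gene1, nodes) - 1L,
                            match(e$gene2, nodes) - 1L,
                            as.numeric(e$distance),
                            isTRUE(normalized))
  names(bc) <- nodes
  bc
}

#' Eigenvector centrality by shifted power iteration
#'
#' Dominant eigenvector of the affinity-weighted (|cc|) adjacency matrix,
#' computed by power iteration on A + cI (the small diagonal shift c breaks
#' the +/-lambda oscillation of bipartite graphs without changing the
#' eigenvectors), rescaled so the maximum entry is 1. Convergence is declared
#' when the relative eigen-residual ||Ax - lambda*x||_inf / lambda falls
#' below \code{tol}. In disconnected graphs the iteration limit concentrates
#' mass on the dominant component; other components decay toward zero and
#' are reported as computed.
#'
#' @param net a \linkS4class{ConditionNetwork} (at least one positive
#'   affinity).
#' @param tol convergence tolerance on the relative residual, default 1e-10.
#' @param maxIter iteration cap, default 10000; non-convergence is an error
#'   reporting the residual.
#' @return named numeric vector in [0, 1] over \code{networkNodes(net)},
#'   maximum entry 1.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 10000L) {
  stopifnot(is(net, "ConditionNetwork"))
  nodes <- networkNodes(net)
  n <- length(nodes)
  e <- networkEdges(net)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(e$gene1, nodes); j <- match(e$gene2, nodes)
  A[cbind(i, j)] <- e$affinity
  A[cbind(j, i)] <- e$affinity
  if (all(A == 0))
    stop("all edge affinities are zero; eigenvector centrality is undefined")
  shift <- 0.1 * max(rowSums(A))
  x <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  prevResid <- Inf
  for (it in seq_len(maxIter)) {
    y <- as.numeric(A %*% x) + shift * x
    y <- y / max(y)
    Ax <- as.numeric(A %*% y)
    lambda <- sum(y * Ax) / sum(y * y)   # Rayleigh quotient on A
    resid <- sqrt(sum((Ax - lambda * y)^2) / sum(y * y))
    x <- y
    ## error bound for power iteration: the angular error is about
    ## resid / gap; estimate the contraction factor from successive
    ## residuals and require the bounded error, not just the residual,
    ## to fall below tol
    contraction <- min(resid / prevResid, 1 - 1e-6)
    prevResid <- resid
    if (lambda > 0 && resid / (lambda * (1 - contraction)) <= tol) {
      out <- x / max(x)
      names(out) <- nodes
      return(out)
    }
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (relative residual %.3g)",
    maxIter, resid / max(lambda, .Machine$double.eps)))
}

#' Per-condition centralities of one network
#'
#' Convenience wrapper returning both measures for one condition network.
#'
#' @param net a \linkS4class{ConditionNetwork}.
#' @param normalizedBetweenness passed to \code{\link{weightedBetweenness}}.
#' @return \code{data.frame} with columns \code{gene}, \code{betweenness},
#'   \code{eigen}.
#' @export
conditionCentralities <- function(net, normalizedBetweenness = FALSE) {
  data.frame(gene = networkNodes(net),
             betweenness = as.numeric(weightedBetweenness(
               net, normalized = normalizedBetweenness)),
             eigen = as.numeric(eigenvectorCentrality(net)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Absolute centrality differences between the two conditions
#'
#' Joins the per-condition tables on their (identical) gene sets and attaches
#' the per-gene absolute differences |B - A| for both measures.
#'
#' @param tableA,tableB outputs of \code{\link{conditionCentralities}} for
#'   the two conditions (identical gene sets required).
#' @param conditions length-2 character vector naming the A and B labels.
#' @return a \linkS4class{CentralityTable}.
#' @export
centralityDeltas <- function(tableA, tableB, conditions = c("A", "B")) {
  if (!setequal(tableA$gene, tableB$gene)) {
    diff <- c(setdiff(tableA$gene, tableB$gene),
              setdiff(tableB$gene, tableA$gene))
    stop("gene sets differ between conditions: ",
         paste(utils::head(diff, 10L), collapse = ", "))
  }
  tableB <- tableB[match(tableA$gene, tableB$gene), , drop = FALSE]
  t <- data.frame(gene = tableA$gene,
                  betweenness_A = tableA$betweenness,
                  betweenness_B = tableB$betweenness,
                  eigen_A = tableA$eigen,
                  eigen_B = tableB$eigen,
                  stringsAsFactors = FALSE, row.names = NULL)
  t$abs_delta_betweenness <- abs(t$betweenness_B - t$betweenness_A)
  t$abs_delta_eigen <- abs(t$eigen_B - t$eigen_A)
  new("CentralityTable", table = t, conditions = as.character(conditions))
}
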