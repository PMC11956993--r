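## Over-representation of the final gene set against user-supplied
## annotation collections (GMT format), via the one-sided hypergeometric
## tail with BH correction. This is a generic local replacement for web
## enrichment services; no term database is bundled.

#' Read annotation gene sets in GMT format
#'
#' One term per line: term id, description, then tab-separated member genes.
#'
#' @param path file path.
#' @return list with \code{sets} (named list of member vectors) and
#'   \code{descriptions} (named character).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 3L
  if (any(short))
    stop("malformed GMT line ", which(short)[1L],
         " (need term, description, >=1 member)")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id: '", ids[duplicated(ids)][1L], "'")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  desc <- vapply(fields, `[[`, character(1L), 2L)
  names(desc) <- ids
  list(sets = sets, descriptions = desc)
}

#' Restrict an annotation collection to a gene universe
#'
#' Drops members outside the universe and removes terms left empty.
#'
#' @param gmt output of \code{\link{readGMT}} (or a compatible list).
#' @param universe character vector of gene ids the analysis can see.
#' @return list with \code{sets}, \code{descriptions}, \code{universe}.
#' @export
makeAnnotationCollection <- function(gmt, universe) {
  universe <- unique(as.character(universe))
  sets <- lapply(gmt$sets, intersect, y = universe)
  keep <- vapply(sets, length, integer(1L)) > 0L
  list(sets = sets[keep],
       descriptions = gmt$descriptions[names(sets)[keep]],
       universe = universe)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, the one-sided tail P(X >= overlap) of the hypergeometric
#' distribution given the universe size, term size and query size, BH-
#' adjusted across terms. Query genes outside the universe are dropped with
#' a warning.
#'
#' @param query character vector of gene ids (e.g.
#'   \code{diceGenes(set)$gene}).
#' @param annotations output of \code{\link{makeAnnotationCollection}}.
#' @param fdrCut adjusted-value cutoff for the \code{significant} flag,
#'   default 0.05.
#' @return \code{data.frame} sorted by ascending p-value with columns
#'   \code{term}, \code{description}, \code{term_size}, \code{query_size},
#'   \code{overlap}, \code{pvalue}, \code{qvalue}, \code{significant}.
#' @export
hypergeometricORA <- function(query, annotations, fdrCut = 0.05) {
  universe <- annotations$universe
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " query gene(s) outside the universe")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query after universe restriction")
  N <- length(universe)
  q <- length(query)
  res <- lapply(names(annotations$sets), function(id) {
    members <- annotations$sets[[id]]
    k <- length(members)
    ov <- length(intersect(members, query))
    data.frame(term = id,
               description = unname(annotations$descriptions[id]),
               term_size = k, query_size = q, overlap = ov,
               pvalue = stats::phyper(ov - 1L, k, N - k, q,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$qvalue <- bhAdjust(res$pvalue)
  res$significant <- res$qvalue < fdrCut
  res <- res[order(res$pvalue, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
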