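#' Construct a DiceExperiment from a matrix and a sample design
#'
#' @param expr numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). Values are assumed to be on a log or
#'   intensity scale and must be finite.
#' @param condition character or factor of length \code{ncol(expr)} with
#'   exactly two distinct labels, or a named vector covering every sample.
#'   The first level (order of appearance unless a factor is supplied) is
#'   the reference condition "A"; log2 fold changes are B minus A.
#' @param pairing optional pairing identifiers (same length/naming rules);
#'   each pairing id must map to exactly one sample per condition.
#' @return a \linkS4class{DiceExperiment}.
#' @examples
#' m <- matrix(rnorm(24), 4, 6,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' de <- DiceExperiment(m, rep(c("normal", "tumor"), each = 3))
#' conditionLabels(de)
#' @export
DiceExperiment <- function(expr, condition, pairing = NULL) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  align <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (!is.null(names(v))) {
      missing <- setdiff(colnames(expr), names(v))
      if (length(missing))
        stop("no ", what, " given for sample(s): ",
             paste(missing, collapse = ", "))
      v <- v[colnames(expr)]
    } else if (length(v) != ncol(expr)) {
      stop(what, " must have one entry per sample")
    }
    v
  }
  condition <- align(condition, "condition")
  if (!is.factor(condition))
    condition <- factor(as.character(condition),
                        levels = unique(as.character(condition)))
  cd <- S4Vectors::DataFrame(condition = condition, row.names = colnames(expr))
  if (!is.null(pairing)) cd$pairing <- as.character(align(pairing, "pairing"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr), colData = cd)
  new("DiceExperiment", se)
}

#' Construct an InteractionSet from an edge table
#'
#' Edges are canonicalized (unordered pairs stored once with gene1 < gene2),
#' reversed duplicates merged keeping the maximum score, self-loops removed,
#' and edges below the confidence threshold dropped.
#'
#' @param gene1,gene2 character vectors of interaction partners.
#' @param score integer combined confidence scores in [0, 1000].
#' @param threshold minimum retained score; default 400 (STRING medium
#'   confidence, retained when score >= threshold).
#' @return an \linkS4class{InteractionSet}.
#' @export
InteractionSet <- function(gene1, gene2, score, threshold = 400L) {
  gene1 <- as.character(gene1); gene2 <- as.character(gene2)
  if (length(gene1) != length(gene2) || length(gene1) != length(score))
    stop("gene1, gene2 and score must have equal length")
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1000))
    stop("interaction scores must lie in [0, 1000]")
  score <- as.integer(round(score))
  keep <- gene1 != gene2
  gene1 <- gene1[keep]; gene2 <- gene2[keep]; score <- score[keep]
  swap <- gene1 > gene2
  tmp <- gene1[swap]; gene1[swap] <- gene2[swap]; gene2[swap] <- tmp
  key <- paste(gene1, gene2, sep = "\r")
  score <- vapply(split(score, key), max, integer(1L))
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  e <- data.frame(gene1 = pairs[, 1L], gene2 = pairs[, 2L],
                  score = as.integer(score), stringsAsFactors = FALSE)
  e <- e[e$score >= threshold, , drop = FALSE]
  e <- e[order(e$gene1, e$gene2), , drop = FALSE]
  rownames(e) <- NULL
  new("InteractionSet", edges = e, threshold = as.integer(threshold))
}

#' Read a gene x sample expression matrix
#'
#' Expects a delimited text file whose first column holds gene identifiers
#' and whose header row holds sample identifiers; all remaining cells must be
#' numeric. Row and column order are preserved.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path, delimiter = "\t") {
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression file: ", path)
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier in ", path, ": '",
         genes[duplicated(genes)][1L], "'")
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s' (row %d), sample '%s' (column %d): '%s'",
      genes[bad[1L, 1L]], bad[1L, 1L], colnames(vals)[bad[1L, 2L]],
      bad[1L, 2L] + 1L, vals[bad[1L, 1L], bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Read a two-group sample design
#'
#' Two- or three-column table: sample_id, condition, optional pairing_id,
#' with a header row. Exactly two condition labels are required.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return \code{data.frame} with columns \code{sample}, \code{condition} and
#'   optionally \code{pairing}.
#' @export
readSampleDesign <- function(path, delimiter = "\t") {
  d <- utils::read.delim(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(d) == 0L || ncol(d) < 2L)
    stop("design file must have at least sample and condition columns: ", path)
  out <- data.frame(sample = d[[1L]], condition = d[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(d) >= 3L) out$pairing <- d[[3L]]
  if (any(out$condition == "" | is.na(out$condition)))
    stop("sample(s) without a condition label: ",
         paste(out$sample[out$condition == "" | is.na(out$condition)],
               collapse = ", "))
  labs <- unique(out$condition)
  if (length(labs) != 2L)
    stop("exactly two condition labels required, got: ",
         paste(labs, collapse = ", "))
  if (anyDuplicated(out$sample))
    stop("duplicate sample identifier: '",
         out$sample[duplicated(out$sample)][1L], "'")
  if (!is.null(out$pairing)) {
    tab <- table(out$pairing, out$condition)
    if (any(tab > 1L))
      stop("pairing id '", rownames(tab)[which(apply(tab, 1L, max) > 1L)[1L]],
           "' maps to more than one sample in one condition")
  }
  out
}

#' Read a STRING-style interaction edge list
#'
#' Three columns (gene1, gene2, combined_score in 0--1000) with a header.
#' Edges below \code{scoreThreshold} are dropped, self-loops removed and
#' reversed duplicates merged keeping the maximum score. Reading the
#' canonicalized output of \code{\link{writeInteractions}} back is the
#' identity.
#'
#' @param path file path.
#' @param scoreThreshold minimum retained combined score, default 400.
#' @param delimiter field separator, default tab.
#' @return an \linkS4class{InteractionSet}.
#' @export
readInteractions <- function(path, scoreThreshold = 400L, delimiter = "\t") {
  d <- utils::read.delim(path, sep = delimiter, header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 3L)
    stop("interaction file must have three columns (gene1, gene2, score): ",
         path)
  sc <- suppressWarnings(as.numeric(d[[3L]]))
  bad <- which(!is.finite(sc) | d[[1L]] == "" | d[[2L]] == "")
  if (length(bad))
    stop("malformed interaction row at line ", bad[1L] + 1L, " of ", path)
  out_of_range <- which(sc < 0 | sc > 1000)
  if (length(out_of_range))
    stop("combined score outside [0, 1000] at line ", out_of_range[1L] + 1L,
         " of ", path, ": ", sc[out_of_range[1L]])
  InteractionSet(d[[1L]], d[[2L]], sc, threshold = scoreThreshold)
}

#' Assemble a DiceExperiment from files
#'
#' Convenience wrapper joining \code{\link{readExpressionMatrix}} and
#' \code{\link{readSampleDesign}}; every design sample must be present in the
#' expression matrix (columns are subset and reordered to the design).
#'
#' @param exprPath,designPath file paths.
#' @param delimiter field separator, default tab.
#' @return a \linkS4class{DiceExperiment}.
#' @export
readDiceExperiment <- function(exprPath, designPath, delimiter = "\t") {
  m <- readExpressionMatrix(exprPath, delimiter)
  d <- readSampleDesign(designPath, delimiter)
  missing <- setdiff(d$sample, colnames(m))
  if (length(missing))
    stop("design sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  m <- m[, d$sample, drop = FALSE]
  DiceExperiment(m, condition = d$condition, pairing = d$pairing)
}

#' Write / export helpers
#'
#' \code{writeResultsTable} writes an \linkS4class{EnsembleRanking} as the
#' canonical 14-column results TSV sorted by final rank, numbers formatted to
#' 6 decimals. \code{writeInteractions} writes an InteractionSet as a
#' canonical 3-column TSV. \code{writeConditionNetwork} writes a weighted
#' edge list (gene1, gene2, cc, distance). \code{writeCentralityTable}
#' writes the gene + 6 numeric centrality columns.
#'
#' @param ranking an \linkS4class{EnsembleRanking} (non-empty).
#' @param x object to export.
#' @param path output file path.
#' @return the path, invisibly.
#' @name exporters
#' @export
writeResultsTable <- function(ranking, path) {
  stopifnot(is(ranking, "EnsembleRanking"))
  t <- rankingTable(ranking)
  if (nrow(t) == 0L) stop("refusing to write an empty ranking")
  cols <- c("gene", "log2fc", "direction", "betweenness_A", "betweenness_B",
            "eigen_A", "eigen_B", "abs_delta_betweenness", "abs_delta_eigen",
            "rank_betweenness", "rank_eigen", "ensemble_score", "final_rank",
            "passed_filter")
  t <- t[order(t$final_rank), cols, drop = FALSE]
  num <- vapply(t, is.numeric, logical(1L)) & colnames(t) != "final_rank"
  t[num] <- lapply(t[num], function(v) sprintf("%.6f", v))
  t$passed_filter <- ifelse(as.logical(t$passed_filter), "TRUE", "FALSE")
  .writeTSV(t, path)
}

#' @rdname exporters
#' @export
writeInteractions <- function(x, path) {
  stopifnot(is(x, "InteractionSet"))
  .writeTSV(interactions(x), path)
}

#' @rdname exporters
#' @export
writeConditionNetwork <- function(x, path) {
  stopifnot(is(x, "ConditionNetwork"))
  e <- networkEdges(x)[, c("gene1", "gene2", "cc", "distance")]
  e$cc <- sprintf("%.6f", e$cc)
  e$distance <- sprintf("%.6f", e$distance)
  .writeTSV(e, path)
}

#' @rdname exporters
#' @export
writeCentralityTable <- function(x, path) {
  stopifnot(is(x, "CentralityTable"))
  t <- centralities(x)
  num <- vapply(t, is.numeric, logical(1L))
  t[num] <- lapply(t[num], function(v) sprintf("%.6g", v))
  .writeTSV(t, path)
}

.writeTSV <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(path)
}
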