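## Phase I: relaxed differential expression builds the candidate pool.
## The built-in engine is a per-gene two-sided t-test (paired or Welch) with
## Benjamini-Hochberg adjustment; tables computed externally (e.g. by limma
## or edgeR) can be imported interchangeably via importDETable().

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped at 1 (wraps
#' \code{stats::p.adjust(method = "BH")} with an input range check).
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene differential expression with relaxed-cutoff screening in mind
#'
#' Computes, for every gene, log2fc = mean(condition B) - mean(condition A)
#' (on the already log-scaled values) and a two-sided p-value from a paired
#' t-test (\code{paired = TRUE}, requires pairing ids) or a Welch t-test,
#' followed by BH adjustment over all genes. Genes that are constant in both
#' groups with zero mean difference get p = 1 by convention; constant data
#' with a nonzero difference get p = 0 (the difference is certain under the
#' model's own variance estimate).
#'
#' @param x a \linkS4class{DiceExperiment} (expression on log2 scale).
#' @param paired logical; use the paired t-test on within-pair differences.
#' @return \code{data.frame} with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}, \code{qvalue}, one row per gene in \code{x}.
#' @export
computeDETable <- function(x, paired = FALSE) {
  stopifnot(is(x, "DiceExperiment"))
  m <- exprMatrix(x)
  cond <- sampleConditions(x)
  labs <- levels(cond)
  a <- m[, cond == labs[1L], drop = FALSE]
  b <- m[, cond == labs[2L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each condition needs at least 2 samples")
  if (paired) {
    p <- pairingIds(x)
    if (is.null(p)) stop("paired = TRUE requires pairing ids in the design")
    pa <- p[cond == labs[1L]]
    pb <- p[cond == labs[2L]]
    if (!setequal(pa, pb))
      stop("pairing ids do not match across conditions")
    b <- b[, match(pa, pb), drop = FALSE]
  }
  ## genes whose data are (numerically) constant get the documented
  ## convention: p = 1 for a zero mean difference, p = 0 otherwise
  convention <- function(meanDiff) if (meanDiff == 0) 1 else 0
  testOne <- function(av, bv) {
    if (paired) {
      d <- bv - av
      if (stats::sd(d) == 0) return(convention(mean(d)))
      tryCatch(stats::t.test(d)$p.value,
               error = function(e) {
                 if (grepl("constant", conditionMessage(e)))
                   convention(mean(d)) else stop(e)
               })
    } else {
      if (stats::sd(av) == 0 && stats::sd(bv) == 0)
        return(convention(mean(bv) - mean(av)))
      tryCatch(stats::t.test(bv, av, var.equal = FALSE)$p.value,
               error = function(e) {
                 if (grepl("constant", conditionMessage(e)))
                   convention(mean(bv) - mean(av)) else stop(e)
               })
    }
  }
  pv <- vapply(seq_len(nrow(m)),
               function(i) testOne(a[i, ], b[i, ]), numeric(1L))
  data.frame(gene = rownames(m),
             log2fc = rowMeans(b) - rowMeans(a),
             pvalue = pv,
             qvalue = bhAdjust(pv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Import an externally computed differential-expression table
#'
#' Accepts a TSV with header columns \code{gene}, \code{log2fc},
#' \code{pvalue} and optionally \code{qvalue} (recomputed by BH when absent),
#' e.g. an export from limma or edgeR, so the downstream phases can run on
#' exactly the statistics such engines produced.
#'
#' @param path file path.
#' @param x optional \linkS4class{DiceExperiment}; genes absent from it are
#'   dropped with a warning.
#' @return \code{data.frame} interchangeable with \code{computeDETable}
#'   output.
#' @export
importDETable <- function(path, x = NULL) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  missing <- setdiff(need, colnames(d))
  if (length(missing))
    stop("DE table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(d$pvalue)) || any(d$pvalue < 0) || any(d$pvalue > 1))
    stop("p-values must lie in [0, 1]")
  if (anyDuplicated(d$gene))
    stop("duplicate gene in DE table: '", d$gene[duplicated(d$gene)][1L], "'")
  if (!is.null(x)) {
    known <- rownames(exprMatrix(x))
    drop <- !(d$gene %in% known)
    if (any(drop)) {
      warning("dropping ", sum(drop),
              " DE-table gene(s) absent from the expression matrix")
      d <- d[!drop, , drop = FALSE]
    }
  }
  if (!"qvalue" %in% colnames(d)) {
    d$qvalue <- bhAdjust(d$pvalue)
  } else if (any(!is.finite(d$qvalue)) || any(d$qvalue < 0) ||
             any(d$qvalue > 1)) {
    stop("q-values must lie in [0, 1]")
  }
  rownames(d) <- NULL
  d[, c("gene", "log2fc", "pvalue", "qvalue")]
}

#' Select the candidate gene pool and z-score it
#'
#' Keeps genes with \code{stat < statCut} and, when \code{lfcCut} is not
#' \code{NULL}, \code{|log2fc| > lfcCut} (both inequalities strict). Retained
#' genes are labelled up/down by the sign of log2fc ("flat" at exactly zero,
#' only reachable with \code{lfcCut = NULL}) and their expression rows are
#' z-scored across all samples pooled. Genes constant across all samples
#' cannot be z-scored and are removed with a warning.
#'
#' @param x a \linkS4class{DiceExperiment}.
#' @param de DE table from \code{\link{computeDETable}} or
#'   \code{\link{importDETable}}.
#' @param statField \code{"qvalue"} (FDR, default) or \code{"pvalue"}.
#' @param statCut strict upper cutoff on \code{statField}; default 0.05.
#' @param lfcCut strict lower cutoff on |log2fc|, or \code{NULL} for no fold
#'   change requirement; default 0.5.
#' @return a \linkS4class{CandidatePool}.
#' @export
selectCandidates <- function(x, de, statField = c("qvalue", "pvalue"),
                             statCut = 0.05, lfcCut = 0.5) {
  stopifnot(is(x, "DiceExperiment"))
  statField <- match.arg(statField)
  if (!is.finite(statCut) || statCut <= 0)
    stop("statCut must be strictly positive")
  if (!is.null(lfcCut) && (!is.finite(lfcCut) || lfcCut < 0))
    stop("lfcCut must be >= 0 or NULL")
  keep <- de[[statField]] < statCut
  if (!is.null(lfcCut)) keep <- keep & abs(de$log2fc) > lfcCut
  sel <- de[keep, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no genes pass the cutoffs (", statField, " < ", statCut,
         if (!is.null(lfcCut)) paste0(", |log2fc| > ", lfcCut),
         "); consider looser cutoffs")
  m <- exprMatrix(x)[sel$gene, , drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("removing ", sum(sds == 0),
            " zero-variance gene(s) before z-scoring: ",
            paste(utils::head(sel$gene[sds == 0], 5L), collapse = ", "))
    sel <- sel[sds > 0, , drop = FALSE]
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(sel) == 0L) stop("no genes left after removing constant rows")
  }
  z <- (m - rowMeans(m)) / sds
  sel$direction <- ifelse(sel$log2fc > 0, "up",
                          ifelse(sel$log2fc < 0, "down", "flat"))
  rownames(sel) <- NULL
  new("CandidatePool",
      stats = sel[, c("gene", "log2fc", "pvalue", "qvalue", "direction")],
      zscores = z,
      cutoffs = list(statField = statField, statCut = statCut,
                     lfcCut = lfcCut))
}
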