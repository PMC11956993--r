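## Phases I-V orchestration, from in-memory objects (dicePipeline) or from a
## flat YAML config with file paths (runDice). Every default actually used is
## echoed into the run log so a run is auditable from its outputs alone.

#' Default pipeline configuration
#'
#' Flat key-value list understood by \code{\link{validateConfig}} and
#' \code{\link{runDice}}. Path keys (\code{expression}, \code{design},
#' \code{interactions}, optional \code{de_table}, \code{gmt}) have no
#' defaults and must be supplied.
#'
#' @return named list of defaults: \code{stat_field} "qvalue",
#'   \code{stat_cut} 0.05, \code{lfc_cut} 0.5 (\code{"none"} disables the
#'   fold-change requirement), \code{paired} FALSE, \code{ig_bins} 10,
#'   \code{ig_strategy} "equal_frequency", \code{score_threshold} 400,
#'   \code{normalize_betweenness} FALSE, \code{filter_mode} "strict",
#'   \code{fdr_cut} 0.05 (enrichment), \code{output_dir} "dice_out",
#'   \code{seed} 1.
#' @export
defaultConfig <- function() {
  list(expression = NULL, design = NULL, interactions = NULL,
       de_table = NULL, gmt = NULL,
       stat_field = "qvalue", stat_cut = 0.05, lfc_cut = 0.5,
       paired = FALSE,
       ig_bins = 10L, ig_strategy = "equal_frequency",
       score_threshold = 400L,
       normalize_betweenness = FALSE,
       filter_mode = "strict",
       fdr_cut = 0.05,
       output_dir = "dice_out",
       seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML with flat keys; unknown keys are an error, missing keys take their
#' defaults.
#'
#' @param path YAML file path.
#' @return merged configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns problems rather than throwing; an empty character vector means
#' the configuration is runnable.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @return character vector of problems, each naming the offending key.
#' @export
validateConfig <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  for (key in c("expression", "design", "interactions")) {
    if (is.null(config[[key]])) add(paste0(key, ": path is required"))
    else if (!file.exists(config[[key]]))
      add(paste0(key, ": file does not exist: ", config[[key]]))
  }
  for (key in c("de_table", "gmt")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      add(paste0(key, ": file does not exist: ", config[[key]]))
  }
  if (!identical(config$stat_field, "qvalue") &&
      !identical(config$stat_field, "pvalue"))
    add("stat_field: must be 'qvalue' or 'pvalue'")
  if (!is.numeric(config$stat_cut) || config$stat_cut <= 0 ||
      config$stat_cut > 1)
    add("stat_cut: must lie in (0, 1]")
  lfc <- config$lfc_cut
  if (!(is.null(lfc) || identical(lfc, "none") ||
        (is.numeric(lfc) && lfc >= 0)))
    add("lfc_cut: must be >= 0 or 'none'")
  if (!is.numeric(config$ig_bins) || config$ig_bins < 2)
    add("ig_bins: must be >= 2")
  if (!config$ig_strategy %in% c("equal_frequency", "equal_width"))
    add("ig_strategy: must be 'equal_frequency' or 'equal_width'")
  if (!is.numeric(config$score_threshold) || config$score_threshold < 0 ||
      config$score_threshold > 1000)
    add("score_threshold: must lie in [0, 1000]")
  if (!config$filter_mode %in% c("strict", "either_measure"))
    add("filter_mode: must be 'strict' or 'either_measure'")
  if (!is.logical(config$normalize_betweenness))
    add("normalize_betweenness: must be logical")
  if (!is.logical(config$paired)) add("paired: must be logical")
  if (!is.numeric(config$fdr_cut) || config$fdr_cut <= 0 ||
      config$fdr_cut > 1)
    add("fdr_cut: must lie in (0, 1]")
  problems
}

#' Run Phases I-V on in-memory objects
#'
#' The pipeline engine: differential expression (computed or imported) and
#' candidate selection, information-gain filtering, condition-network
#' construction and pruning, centralities and their absolute differences,
#' ensemble ranking with the exclusion filter. Deterministic given fixed
#' inputs and parameters.
#'
#' @param x a \linkS4class{DiceExperiment}.
#' @param interactionSet an \linkS4class{InteractionSet}.
#' @param deTable optional externally computed DE table (see
#'   \code{\link{importDETable}}); computed internally when \code{NULL}.
#' @param paired passed to \code{\link{computeDETable}}.
#' @param statField,statCut,lfcCut Phase I cutoffs (see
#'   \code{\link{selectCandidates}}).
#' @param igBins,igStrategy Phase II settings.
#' @param normalizeBetweenness Phase IV flag.
#' @param filterMode Phase V exclusion-filter mode.
#' @param igFallbackKeepAll passed to \code{\link{selectByMeanIG}}.
#' @return list with \code{diceGenes} (\linkS4class{DiceGeneSet}),
#'   \code{ranking}, \code{centrality}, \code{networks} (list A/B),
#'   \code{pool}, \code{igTable}, \code{deTable} and \code{report} (the
#'   per-phase gene-count \code{data.frame}).
#' @export
dicePipeline <- function(x, interactionSet, deTable = NULL, paired = FALSE,
                         statField = "qvalue", statCut = 0.05, lfcCut = 0.5,
                         igBins = 10L, igStrategy = "equal_frequency",
                         normalizeBetweenness = FALSE,
                         filterMode = "strict",
                         igFallbackKeepAll = FALSE) {
  phase <- function(name, nIn, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    list(result = res,
         row = data.frame(phase = name, n_in = nIn, n_out = NA_integer_,
                          seconds = round(proc.time()[["elapsed"]] - t0, 3L),
                          stringsAsFactors = FALSE))
  }
  report <- list()

  nGenes <- nrow(exprMatrix(x))
  p1 <- phase("I_differential_expression", nGenes, function() {
    de <- if (is.null(deTable)) computeDETable(x, paired = paired)
          else deTable
    selectCandidates(x, de,
                     statField = statField, statCut = statCut,
                     lfcCut = lfcCut)
  })
  pool <- p1$result
  p1$row$n_out <- length(poolGenes(pool))
  report$I <- p1$row

  p2 <- phase("II_information_gain", length(poolGenes(pool)), function() {
    igTable <- informationGainTable(pool, x, nBins = igBins,
                                    strategy = igStrategy)
    list(igTable = igTable,
         genes = selectByMeanIG(igTable,
                                fallbackKeepAll = igFallbackKeepAll))
  })
  igTable <- p2$result$igTable
  igGenes <- p2$result$genes
  if (length(igGenes) == 0L)
    stop("[II_information_gain] no gene exceeds the mean information gain")
  p2$row$n_out <- length(igGenes)
  report$II <- p2$row

  labs <- conditionLabels(x)
  p3 <- phase("III_condition_networks", length(igGenes), function() {
    netA <- buildConditionNetwork(igGenes, x, interactionSet, labs[1L])
    netB <- buildConditionNetwork(igGenes, x, interactionSet, labs[2L])
    pruneUnconnected(netA, netB)
  })
  nets <- p3$result
  p3$row$n_out <- length(networkNodes(nets$A))
  report$III <- p3$row

  p4 <- phase("IV_centralities", length(networkNodes(nets$A)), function() {
    centralityDeltas(
      conditionCentralities(nets$A,
                            normalizedBetweenness = normalizeBetweenness),
      conditionCentralities(nets$B,
                            normalizedBetweenness = normalizeBetweenness),
      conditions = labs)
  })
  ct <- p4$result
  p4$row$n_out <- nrow(centralities(ct))
  report$IV <- p4$row

  p5 <- phase("V_ensemble_ranking", nrow(centralities(ct)), function() {
    ranking <- ensembleRanking(ct, pool, filterMode = filterMode)
    list(ranking = ranking, genes = assembleDiceGenes(ranking, pool))
  })
  ranking <- p5$result$ranking
  geneSet <- p5$result$genes
  p5$row$n_out <- nrow(diceGenes(geneSet))
  report$V <- p5$row

  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  ## each phase filters or preserves the running gene set
  stopifnot(all(diff(report$n_out) <= 0))
  list(diceGenes = geneSet, ranking = ranking, centrality = ct,
       networks = nets, pool = pool, igTable = igTable, deTable = deTable,
       report = report)
}

#' Run the full pipeline from a configuration
#'
#' Reads the input files named in \code{config}, executes Phases I-V (plus
#' over-representation when a GMT file is configured), and writes
#' \code{results.tsv}, \code{centrality.tsv}, \code{phase_report.json},
#' \code{run.log} and optionally \code{enrichment.tsv} into the output
#' directory.
#'
#' @param config configuration list (see \code{\link{defaultConfig}} /
#'   \code{\link{readRunConfig}}); validated first, problems are an error.
#' @return the \code{\link{dicePipeline}} result list, with an extra
#'   \code{enrichment} element when ORA ran, invisibly.
#' @export
runDice <- function(config) {
  cfg <- defaultConfig()
  cfg[names(config)] <- config
  problems <- validateConfig(cfg)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  lfcCut <- if (is.null(cfg$lfc_cut) || identical(cfg$lfc_cut, "none"))
    NULL else cfg$lfc_cut

  x <- readDiceExperiment(cfg$expression, cfg$design)
  ints <- readInteractions(cfg$interactions,
                           scoreThreshold = cfg$score_threshold)
  deTable <- if (is.null(cfg$de_table)) NULL else
    importDETable(cfg$de_table, x)

  res <- dicePipeline(x, ints, deTable = deTable, paired = cfg$paired,
                      statField = cfg$stat_field, statCut = cfg$stat_cut,
                      lfcCut = lfcCut, igBins = cfg$ig_bins,
                      igStrategy = cfg$ig_strategy,
                      normalizeBetweenness = cfg$normalize_betweenness,
                      filterMode = cfg$filter_mode)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeResultsTable(res$ranking, file.path(cfg$output_dir, "results.tsv"))
  writeCentralityTable(res$centrality,
                       file.path(cfg$output_dir, "centrality.tsv"))
  jsonlite::write_json(res$report,
                       file.path(cfg$output_dir, "phase_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  if (!is.null(cfg$gmt)) {
    ann <- makeAnnotationCollection(readGMT(cfg$gmt),
                                    universe = rownames(exprMatrix(x)))
    res$enrichment <- hypergeometricORA(diceGenes(res$diceGenes)$gene, ann,
                                        fdrCut = cfg$fdr_cut)
    .writeTSV(within(res$enrichment, {
      pvalue <- sprintf("%.6g", pvalue); qvalue <- sprintf("%.6g", qvalue)
    }), file.path(cfg$output_dir, "enrichment.tsv"))
  }

  settings <- cfg[!vapply(cfg, is.null, logical(1L))]
  log <- c("dicenet run",
           paste0("  ", names(settings), " = ",
                  vapply(settings, function(v) paste(format(v), collapse = ","),
                         character(1L))),
           "phase gene counts:",
           sprintf("  %s: %d -> %d (%.3fs)", res$report$phase,
                   res$report$n_in, res$report$n_out, res$report$seconds))
  writeLines(log, file.path(cfg$output_dir, "run.log"))
  invisible(res)
}
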