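## Synthetic two-condition data with planted differential expression and
## differential co-expression, plus a matching interaction scaffold. Genes
## are partitioned into correlation modules; a few whole "signal" modules
## carry a mean shift in condition B, and a subset of their genes ("rewired
## hubs") additionally lose (or flip) their within-module correlation in
## condition B only -- the signal the centrality phases must detect.

#' Simulate a two-condition dataset with planted network signal
#'
#' Within each module, expression is multivariate normal with pairwise
#' correlation \code{rho} and marginal standard deviation \code{sigma} (so
#' realized pair correlations match \code{rho}). The first \code{nDE} genes
#' (whole leading modules when \code{nDE} is a multiple of the module size)
#' receive a mean shift of magnitude \code{delta} in condition B, with the
#' sign alternating by module so both up- and down-regulation are planted.
#' \code{nRewired} of the shifted genes, spread evenly over the signal
#' modules, are decorrelated from their module (\code{rewireMode = "zero"})
#' or anti-correlated (\code{"flip"}) in condition B; the planted rewired
#' set therefore overlaps the planted DE set by construction, and the
#' overlap is recorded in the returned truth. The interaction scaffold
#' contains every within-module pair (score 999) plus random cross-module
#' edges (score 450), \code{crossFrac} of the within-module edge count.
#'
#' @param nGenes total genes (>= 5 per module).
#' @param nPerCondition samples per condition (>= 10).
#' @param nModules number of correlation modules; default 20.
#' @param rho within-module pairwise correlation in (0, 1); default 0.7.
#' @param delta expression shift magnitude for DE genes; default 1.
#' @param sigma marginal standard deviation (> 0); default 1.
#' @param nRewired number of rewired hub genes; default 20.
#' @param nDE number of shifted genes; default 100.
#' @param crossFrac cross-module edges as a fraction of within-module edges;
#'   default 0.05.
#' @param rewireMode \code{"zero"} (decorrelate) or \code{"flip"}
#'   (anti-correlate; errors when the implied correlation matrix is not
#'   positive semi-definite).
#' @param conditionNames length-2 labels, default \code{c("A", "B")}; the
#'   shift is applied in the second.
#' @param seed integer master seed; identical seeds reproduce the dataset
#'   bit-identically.
#' @return list with \code{experiment} (\linkS4class{DiceExperiment}),
#'   \code{interactions} (\linkS4class{InteractionSet}) and \code{truth}
#'   (planted DE genes and signed shifts, rewired genes, their overlap,
#'   module memberships, parameters).
#' @export
simulateDiceData <- function(nGenes = 500L, nPerCondition = 30L,
                             nModules = 20L, rho = 0.7, delta = 1,
                             sigma = 1, nRewired = 20L, nDE = 100L,
                             crossFrac = 0.05,
                             rewireMode = c("zero", "flip"),
                             conditionNames = c("A", "B"), seed = 1L) {
  rewireMode <- match.arg(rewireMode)
  if (nGenes < nModules * 5L)
    stop("nGenes must be at least 5 per module")
  if (nPerCondition < 10L) stop("nPerCondition must be >= 10")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (nDE > nGenes) stop("nDE cannot exceed nGenes")
  if (nRewired > nDE)
    stop("nRewired cannot exceed nDE (rewired hubs are drawn from the ",
         "shifted genes so they survive the differential-expression screen)")
  set.seed(as.integer(seed))

  genes <- sprintf("g%04d", seq_len(nGenes))
  moduleOf <- sort(rep_len(seq_len(nModules), nGenes))
  names(moduleOf) <- genes

  ## planted DE: first nDE genes; shift sign alternates by module
  deGenes <- genes[seq_len(nDE)]
  shifts <- delta * ifelse(moduleOf[deGenes] %% 2L == 1L, 1, -1)
  names(shifts) <- deGenes

  ## rewired hubs: round-robin over the signal modules, inside the DE set
  rewired <- character(0)
  if (nRewired > 0L) {
    sigMods <- unique(moduleOf[deGenes])
    byMod <- split(deGenes, moduleOf[deGenes])[as.character(sigMods)]
    taken <- integer(length(byMod))
    for (i in seq_len(nRewired)) {
      m <- ((i - 1L) %% length(byMod)) + 1L
      while (taken[m] >= length(byMod[[m]])) m <- (m %% length(byMod)) + 1L
      taken[m] <- taken[m] + 1L
      rewired <- c(rewired, byMod[[m]][taken[m]])
    }
  }

  moduleCor <- function(size, rewiredIdx) {
    R <- matrix(rho, size, size)
    diag(R) <- 1
    if (length(rewiredIdx)) {
      off <- if (rewireMode == "zero") 0 else -rho
      R[rewiredIdx, ] <- off
      R[, rewiredIdx] <- off
      R[rewiredIdx, rewiredIdx] <- if (rewireMode == "zero") 0 else rho
      diag(R) <- 1
    }
    R
  }
  checkPSD <- function(R, m) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      stop("module ", m, " correlation matrix is not positive semi-definite",
           " (min eigenvalue ", signif(ev, 3), "); ",
           "rewireMode = 'flip' is infeasible at this rho/module size")
    R
  }

  drawCondition <- function(rewiredHere) {
    out <- matrix(NA_real_, nGenes, nPerCondition)
    for (m in seq_len(nModules)) {
      idx <- which(moduleOf == m)
      rIdx <- which(genes[idx] %in% rewiredHere)
      R <- checkPSD(moduleCor(length(idx), rIdx), m)
      out[idx, ] <- t(MASS::mvrnorm(nPerCondition, mu = rep(0, length(idx)),
                                    Sigma = sigma^2 * R))
    }
    out
  }

  xA <- drawCondition(character(0))
  xB <- drawCondition(rewired)
  xB[match(deGenes, genes), ] <- xB[match(deGenes, genes), ] + shifts
  expr <- cbind(xA, xB)
  dimnames(expr) <- list(genes,
                         c(sprintf("%s_s%02d", conditionNames[1L],
                                   seq_len(nPerCondition)),
                           sprintf("%s_s%02d", conditionNames[2L],
                                   seq_len(nPerCondition))))
  experiment <- DiceExperiment(
    expr, condition = rep(conditionNames, each = nPerCondition))

  ## scaffold: complete within-module graphs + random cross-module edges
  within <- do.call(rbind, lapply(seq_len(nModules), function(m) {
    idx <- genes[moduleOf == m]
    if (length(idx) < 2L) return(NULL)
    t(utils::combn(idx, 2L))
  }))
  nCross <- round(crossFrac * nrow(within))
  cross <- matrix(character(0), 0L, 2L)
  if (nCross > 0L) {
    seen <- character(0)
    while (nrow(cross) < nCross) {
      cand <- matrix(genes[sample.int(nGenes, 2L * nCross, replace = TRUE)],
                     ncol = 2L)
      ok <- moduleOf[cand[, 1L]] != moduleOf[cand[, 2L]]
      cand <- cand[ok, , drop = FALSE]
      swap <- cand[, 1L] > cand[, 2L]
      cand[swap, ] <- cand[swap, 2:1]
      key <- paste(cand[, 1L], cand[, 2L])
      fresh <- !duplicated(key) & !(key %in% seen)
      cand <- cand[fresh, , drop = FALSE]
      take <- utils::head(seq_len(nrow(cand)), nCross - nrow(cross))
      cross <- rbind(cross, cand[take, , drop = FALSE])
      seen <- c(seen, key[fresh][take])
    }
  }
  interactions <- InteractionSet(
    gene1 = c(within[, 1L], cross[, 1L]),
    gene2 = c(within[, 2L], cross[, 2L]),
    score = c(rep(999L, nrow(within)), rep(450L, nrow(cross))),
    threshold = 400L)

  list(experiment = experiment,
       interactions = interactions,
       truth = list(deGenes = deGenes, shifts = shifts,
                    rewiredGenes = rewired,
                    overlap = intersect(deGenes, rewired),
                    modules = moduleOf,
                    params = list(nGenes = nGenes,
                                  nPerCondition = nPerCondition,
                                  nModules = nModules, rho = rho,
                                  delta = delta, sigma = sigma,
                                  nRewired = nRewired, nDE = nDE,
                                  crossFrac = crossFrac,
                                  rewireMode = rewireMode, seed = seed)))
}

#' Write the bundled-style small fixture to disk
#'
#' Generates a compact dataset (default: 50 genes, 10 + 10 samples, 5
#' modules, 4 rewired hubs among 20 shifted genes with delta = 2) and writes
#' plain-text \code{expression.tsv}, \code{design.tsv},
#' \code{interactions.tsv} and \code{truth.tsv} into \code{dir}. Expression
#' values are written to 6 decimals; reading the files back is deterministic.
#'
#' @param dir output directory (created if needed).
#' @param nGenes,nPerCondition,nModules,rho,delta,sigma,nRewired,nDE
#'   generator settings, see \code{\link{simulateDiceData}}.
#' @param crossFrac,seed generator settings.
#' @return the directory path, invisibly.
#' @export
writeSyntheticFixture <- function(dir, nGenes = 50L, nPerCondition = 10L,
                                  nModules = 5L, rho = 0.7, delta = 2,
                                  sigma = 1, nRewired = 4L, nDE = 20L,
                                  crossFrac = 0.05, seed = 1234L) {
  sim <- simulateDiceData(nGenes = nGenes, nPerCondition = nPerCondition,
                          nModules = nModules, rho = rho, delta = delta,
                          sigma = sigma, nRewired = nRewired, nDE = nDE,
                          crossFrac = crossFrac, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- exprMatrix(sim$experiment)
  ex <- data.frame(gene = rownames(m),
                   matrix(sprintf("%.6f", m), nrow = nrow(m),
                          dimnames = list(NULL, colnames(m))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTSV(ex, file.path(dir, "expression.tsv"))
  .writeTSV(data.frame(sample = colnames(m),
                       condition = as.character(
                         sampleConditions(sim$experiment))),
            file.path(dir, "design.tsv"))
  .writeTSV(interactions(sim$interactions),
            file.path(dir, "interactions.tsv"))
  tr <- sim$truth
  .writeTSV(data.frame(gene = names(tr$modules),
                       module = as.integer(tr$modules),
                       shift = ifelse(names(tr$modules) %in% tr$deGenes,
                                      tr$shifts[names(tr$modules)], 0),
                       rewired = names(tr$modules) %in% tr$rewiredGenes),
            file.path(dir, "truth.tsv"))
  invisible(dir)
}
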