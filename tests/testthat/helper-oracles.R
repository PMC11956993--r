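## Independent oracles and small fixture builders shared across the suite.
## The oracles are deliberately naive (enumeration, explicit double sums) and
## never call the code paths they check.

# build a ConditionNetwork directly from an edge table (test plumbing)
makeNet <- function(nodes, gene1, gene2, distance = NULL, cc = NULL,
                    condition = "A") {
  if (is.null(cc)) cc <- 1 - distance
  if (is.null(distance)) distance <- 1 - abs(cc)
  new("ConditionNetwork", condition = condition,
      nodes = as.character(nodes),
      edges = data.frame(gene1 = as.character(gene1),
                         gene2 = as.character(gene2),
                         cc = cc, affinity = abs(cc), distance = distance,
                         stringsAsFactors = FALSE))
}

# random connected weighted graph: random recursive tree plus extra edges;
# weights drawn from a small discrete set so shortest-path ties occur
randomConnectedGraph <- function(n, extraFrac = 0.5,
                                 weightPool = c(0.2, 0.3, 0.4, 0.6, 1)) {
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {
    from <- c(from, sample.int(v - 1L, 1L)); to <- c(to, v)
  }
  nExtra <- round(extraFrac * n)
  if (nExtra > 0) {
    all <- t(utils::combn(n, 2L))
    key <- paste(pmin(from, to), pmax(from, to))
    cand <- all[!(paste(all[, 1L], all[, 2L]) %in% key), , drop = FALSE]
    if (nrow(cand)) {
      take <- cand[sample.int(nrow(cand), min(nExtra, nrow(cand))), ,
                   drop = FALSE]
      from <- c(from, take[, 1L]); to <- c(to, take[, 2L])
    }
  }
  data.frame(from = from, to = to,
             w = sample(weightPool, length(from), replace = TRUE))
}

# random affinity-weighted connected graph whose top two eigenvalues are
# separated: the dominant eigenvector (what the oracle compares) is only
# well-conditioned when the spectral gap is not degenerate
randomGappedGraph <- function(n, minGap = 0.02) {
  repeat {
    g <- randomConnectedGraph(n)
    aff <- runif(nrow(g), 0.05, 1)
    A <- matrix(0, n, n)
    A[cbind(g$from, g$to)] <- aff
    A[cbind(g$to, g$from)] <- aff
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    if ((ev[1] - ev[2]) / ev[1] >= minGap)
      return(list(g = g, aff = aff, A = A))
  }
}

# exhaustive betweenness: enumerate every simple path between every pair,
# identify minimum-distance paths with tolerance, split credit fractionally
bruteBetweenness <- function(n, from, to, w, tol = 1e-9) {
  adj <- lapply(seq_len(n), function(i) {
    nb <- c(to[from == i], from[to == i])
    wt <- c(w[from == i], w[to == i])
    list(nb = nb, wt = wt)
  })
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    paths <- list(); lens <- numeric(0)
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- visited
        lens[length(lens) + 1L] <<- len
        return(invisible())
      }
      a <- adj[[v]]
      for (k in seq_along(a$nb)) {
        u <- a$nb[k]
        if (!(u %in% visited)) walk(u, c(visited, u), len + a$wt[k])
      }
    }
    walk(s, s, 0)
    if (!length(paths)) next
    best <- min(lens)
    sel <- which(lens <= best + tol)
    for (i in sel) {
      interior <- setdiff(paths[[i]], c(s, t))
      bc[interior] <- bc[interior] + 1 / length(sel)
    }
  }
  bc
}

# direct evaluation of the entropy / weighted-entropy / gain formulas,
# written with explicit loops, independent of the package implementation
oracleClassEntropy <- function(labels) {
  D <- 0
  for (cl in unique(labels)) {
    p <- sum(labels == cl) / length(labels)
    if (p > 0) D <- D - p * log2(p)
  }
  D
}
oracleWeightedEntropy <- function(bins, labels) {
  N <- length(bins); we <- 0
  for (v in unique(bins)) {
    inBin <- labels[bins == v]
    we <- we + length(inBin) / N * oracleClassEntropy(inBin)
  }
  we
}
oracleIG <- function(bins, labels) {
  max(oracleClassEntropy(labels) - oracleWeightedEntropy(bins, labels), 0)
}

# independent re-implementation of the below-mean-centrality exclusion rule
oracleFilter <- function(tab, mode) {
  mb_a <- mean(tab$betweenness_A); mb_b <- mean(tab$betweenness_B)
  me_a <- mean(tab$eigen_A);       me_b <- mean(tab$eigen_B)
  out <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    okA_b <- tab$betweenness_A[i] >= mb_a
    okB_b <- tab$betweenness_B[i] >= mb_b
    okA_e <- tab$eigen_A[i] >= me_a
    okB_e <- tab$eigen_B[i] >= me_b
    out[i] <- if (mode == "strict") okA_b && okB_b && okA_e && okB_e
              else (okA_b || okA_e) && (okB_b || okB_e)
  }
  out
}

# angle between two direction vectors via the chord length (acos of a
# near-1 cosine cannot resolve angles below ~1.5e-8 in double precision)
angleBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- min(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2)))
  2 * asin(min(d / 2, 1))
}

# small deterministic two-condition experiment for hand-checked cases
toyExperiment <- function(nGenes = 6L, nPer = 4L, seed = 99L) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * 2L * nPer), nGenes, 2L * nPer,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(2L * nPer))))
  DiceExperiment(m, condition = rep(c("N", "T"), each = nPer))
}

fixturePath <- function(file) {
  system.file("extdata", "fixture50", file, package = "dicenet",
              mustWork = TRUE)
}

fixtureConfig <- function(outDir) {
  cfg <- defaultConfig()
  cfg$expression <- fixturePath("expression.tsv")
  cfg$design <- fixturePath("design.tsv")
  cfg$interactions <- fixturePath("interactions.tsv")
  cfg$output_dir <- outDir
  cfg
}
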