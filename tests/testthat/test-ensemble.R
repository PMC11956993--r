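test_that("descending average-tie ranks follow the convention", {
  expect_equal(rankDescending(c(5, 3, 3, 1)), c(1, 2.5, 2.5, 4))
  set.seed(1)
  v <- rnorm(20)
  expect_setequal(rankDescending(v), 1:20)
  expect_equal(rankDescending(rep(2, 5)), rep(3, 5))
  expect_error(rankDescending(numeric(0)), "empty")
})

test_that("rank aggregation averages, breaks ties totally and commutes", {
  agg <- aggregateRanks(c(1, 3, 2), c(3, 1, 2), genes = c("x", "y", "z"))
  expect_equal(agg$ensemble_score, c(2, 2, 2))
  expect_setequal(agg$final_rank, 1:3)  # total order despite full score tie
  # tie-break prefers the larger betweenness delta, then gene id
  agg2 <- aggregateRanks(c(1, 3, 2), c(3, 1, 2), genes = c("x", "y", "z"),
                         tieBreak = c(0, 5, 0))
  expect_equal(agg2$final_rank[agg2$gene == "y"], 1L)
  # symmetry in the two input rankings
  aggBA <- aggregateRanks(c(3, 1, 2), c(1, 3, 2), genes = c("x", "y", "z"))
  expect_equal(agg$ensemble_score, aggBA$ensemble_score)
  expect_error(aggregateRanks(1:2, 1:3, genes = c("a", "b")), "length")
})

test_that("rank aggregation satisfies unanimity on random inputs", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    rb <- rankDescending(rnorm(n))
    re <- rankDescending(rnorm(n))
    agg <- aggregateRanks(rb, re, genes = sprintf("g%02d", 1:n))
    for (j in sample(n, 5)) for (k in sample(n, 5)) {
      if (rb[j] < rb[k] && re[j] < re[k])
        expect_lt(agg$final_rank[j], agg$final_rank[k])
    }
  }
})

test_that("the centrality-mean filter excludes any below-average value in strict mode", {
  tab <- data.frame(gene = c("hi", "loA", "loE"),
                    betweenness_A = c(10, 1, 10), betweenness_B = c(10, 10, 10),
                    eigen_A = c(0.9, 0.9, 0.9), eigen_B = c(0.9, 0.9, 0.1))
  tab$abs_delta_betweenness <- abs(tab$betweenness_B - tab$betweenness_A)
  tab$abs_delta_eigen <- abs(tab$eigen_B - tab$eigen_A)
  ct <- new("CentralityTable", table = tab, conditions = c("A", "B"))
  strict <- centralityMeanFilter(ct, "strict")
  expect_identical(strict, c(TRUE, FALSE, FALSE))
  either <- centralityMeanFilter(ct, "either_measure")
  # loA is rescued by its above-mean eigen_A; loE by betweenness_B
  expect_identical(either, c(TRUE, TRUE, TRUE))
  expect_true(all(strict <= either))  # strict mode is never more permissive
})

test_that("the filter agrees with an independent re-implementation", {
  set.seed(5)
  for (i in 1:50) {
    n <- 200
    tab <- data.frame(gene = sprintf("g%03d", 1:n),
                      betweenness_A = rlnorm(n), betweenness_B = rlnorm(n),
                      eigen_A = rbeta(n, 2, 5), eigen_B = rbeta(n, 2, 5))
    tab$abs_delta_betweenness <- abs(tab$betweenness_B - tab$betweenness_A)
    tab$abs_delta_eigen <- abs(tab$eigen_B - tab$eigen_A)
    ct <- new("CentralityTable", table = tab, conditions = c("A", "B"))
    for (mode in c("strict", "either_measure"))
      expect_identical(centralityMeanFilter(ct, mode),
                       oracleFilter(tab, mode))
  }
})

test_that("ensemble ranking assembles, filters and re-densifies the gene set", {
  sim <- simulateDiceData(nGenes = 50L, nPerCondition = 10L, nModules = 5L,
                          delta = 2, nRewired = 4L, nDE = 20L, seed = 1234L)
  res <- dicePipeline(sim$experiment, sim$interactions,
                      filterMode = "either_measure")
  rk <- rankingTable(res$ranking)
  expect_setequal(rk$final_rank, seq_len(nrow(rk)))
  dg <- diceGenes(res$diceGenes)
  expect_identical(dg$dice_rank, seq_len(nrow(dg)))
  expect_identical(dg$final_rank, sort(dg$final_rank))
  expect_true(all(dg$gene %in% poolGenes(res$pool)))
  # direction labels agree with log2fc signs
  expect_true(all(dg$direction[dg$log2fc > 0] == "up"))
  expect_true(all(dg$direction[dg$log2fc < 0] == "down"))
})

test_that("an empty survivor set is an error advising the permissive mode", {
  tab <- data.frame(gene = c("a", "b"),
                    betweenness_A = c(0, 10), betweenness_B = c(10, 0),
                    eigen_A = c(0.1, 0.9), eigen_B = c(0.9, 0.1))
  tab$abs_delta_betweenness <- abs(tab$betweenness_B - tab$betweenness_A)
  tab$abs_delta_eigen <- abs(tab$eigen_B - tab$eigen_A)
  ct <- new("CentralityTable", table = tab, conditions = c("A", "B"))
  zrow <- as.numeric(scale(1:4))
  pool <- new("CandidatePool",
              stats = data.frame(gene = c("a", "b"), log2fc = c(1, -1),
                                 pvalue = 0.01, qvalue = 0.01,
                                 direction = c("up", "down")),
              zscores = matrix(rep(zrow, each = 2), 2, 4,
                               dimnames = list(c("a", "b"), paste0("s", 1:4))),
              cutoffs = list(statField = "qvalue", statCut = 0.05,
                             lfcCut = 0.5))
  rk <- ensembleRanking(ct, pool, filterMode = "strict")
  expect_error(assembleDiceGenes(rk, pool), "either_measure")
})

test_that("swapping condition labels leaves the gene set unchanged", {
  sim <- simulateDiceData(nGenes = 50L, nPerCondition = 10L, nModules = 5L,
                          delta = 2, nRewired = 4L, nDE = 20L, seed = 77L)
  x <- sim$experiment
  m <- exprMatrix(x)
  cond <- as.character(sampleConditions(x))
  swapped <- DiceExperiment(m, factor(cond, levels = c("B", "A")))
  run <- function(xx) {
    de <- computeDETable(xx)
    pool <- selectCandidates(xx, de)
    genes <- selectByMeanIG(informationGainTable(pool, xx))
    labs <- conditionLabels(xx)
    nets <- pruneUnconnected(
      buildConditionNetwork(genes, xx, sim$interactions, labs[1]),
      buildConditionNetwork(genes, xx, sim$interactions, labs[2]))
    ct <- centralityDeltas(conditionCentralities(nets$A),
                           conditionCentralities(nets$B), labs)
    rk <- ensembleRanking(ct, pool, "either_measure")
    sort(diceGenes(rk)$gene)
  }
  expect_identical(run(x), run(swapped))
})
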