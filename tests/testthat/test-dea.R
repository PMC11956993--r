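test_that("paired design with a constant shift gives exact log2fc and small p", {
  set.seed(1)
  base <- matrix(rnorm(5 * 4), 5, 4)
  m <- cbind(base, base + 1)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:8))
  x <- DiceExperiment(m, rep(c("N", "T"), each = 4),
                      pairing = rep(paste0("p", 1:4), 2))
  de <- computeDETable(x, paired = TRUE)
  expect_equal(de$log2fc, rep(1, 5))
  # within-pair differences are constant (sd 0, mean 1): certain by convention
  expect_equal(de$pvalue, rep(0, 5))

  # non-degenerate paired case: shift + per-pair noise, n = 4 pairs
  set.seed(2)
  m2 <- cbind(base, base + 1 + matrix(rnorm(20, sd = 0.1), 5, 4))
  dimnames(m2) <- dimnames(m)
  x2 <- DiceExperiment(m2, rep(c("N", "T"), each = 4),
                       pairing = rep(paste0("p", 1:4), 2))
  de2 <- computeDETable(x2, paired = TRUE)
  expect_true(all(de2$pvalue < 0.05))
})

test_that("identical groups give log2fc 0 and p 1", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 4), 4, 4, byrow = FALSE)
  m <- cbind(m, m)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:8))
  x <- DiceExperiment(m, rep(c("A", "B"), each = 4))
  de <- computeDETable(x)
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$pvalue, rep(1, 4))
})

test_that("unpaired p-values match the textbook Welch formula", {
  set.seed(7)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  x <- DiceExperiment(m, rep(c("A", "B"), each = 6))
  de <- computeDETable(x)
  for (i in 1:10) {
    a <- m[i, 1:6]; b <- m[i, 7:12]
    va <- var(a) / 6; vb <- var(b) / 6
    tstat <- (mean(b) - mean(a)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / 5 + vb^2 / 5)
    expect_equal(de$pvalue[i], 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches hand-computed and brute-force step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")

  bruteBH <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    adj <- p[o] * n / (n - seq_along(p) + 1L)
    pmin(1, cummin(adj))[order(o)]
  }
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("imported DE tables are interchangeable with computed ones", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tpvalue",
               paste(paste0("g", 1:5), c(1, -2, 0.3, 0.8, -0.1),
                     c(0.001, 0.01, 0.2, 0.04, 0.9), sep = "\t")), f)
  de <- importDETable(f)
  expect_equal(nrow(de), 5L)
  expect_equal(de$qvalue, bhAdjust(de$pvalue))

  writeLines(c("gene\tlog2fc\tpvalue", "g1\t1\t1.5"), f)
  expect_error(importDETable(f), "\\[0, 1\\]")
  writeLines(c("gene\tlog2fc", "g1\t1"), f)
  expect_error(importDETable(f), "pvalue")

  # genes unknown to the experiment are dropped with a warning
  x <- toyExperiment()
  writeLines(c("gene\tlog2fc\tpvalue",
               "g01\t1\t0.01", "notagene\t2\t0.02"), f)
  expect_warning(de2 <- importDETable(f, x), "absent")
  expect_identical(de2$gene, "g01")
})

test_that("candidate selection applies strict cutoffs and labels direction", {
  x <- toyExperiment(nGenes = 3L)
  de <- data.frame(gene = c("g01", "g02", "g03"),
                   log2fc = c(0.6, 0.5, -0.7),
                   pvalue = c(0.01, 0.01, 0.02),
                   qvalue = c(0.04, 0.04, 0.04))
  pool <- selectCandidates(x, de, statField = "qvalue",
                           statCut = 0.05, lfcCut = 0.5)
  # |lfc| = 0.5 fails the strict > 0.5 boundary
  expect_setequal(poolGenes(pool), c("g01", "g03"))
  st <- poolStats(pool)
  expect_equal(st$direction[st$gene == "g01"], "up")
  expect_equal(st$direction[st$gene == "g03"], "down")

  # p-value mode without a fold-change cutoff
  pool2 <- selectCandidates(x, de, statField = "pvalue",
                            statCut = 0.05, lfcCut = NULL)
  expect_setequal(poolGenes(pool2), c("g01", "g02", "g03"))

  expect_error(selectCandidates(x, de, statCut = 1e-6), "looser")
})

test_that("pool z-scores have mean 0 / sd 1 and constant genes are removed", {
  x <- toyExperiment(nGenes = 5L)
  m <- exprMatrix(x)
  m["g05", ] <- 3  # constant across all samples
  x2 <- DiceExperiment(m, sampleConditions(x))
  de <- data.frame(gene = rownames(m), log2fc = 1,
                   pvalue = 0.01, qvalue = 0.01)
  expect_warning(pool <- selectCandidates(x2, de, lfcCut = NULL), "g05")
  z <- poolZScores(pool)
  expect_false("g05" %in% rownames(z))
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("loosening either cutoff yields a superset pool", {
  sim <- simulateDiceData(nGenes = 100L, nPerCondition = 10L, nModules = 4L,
                          delta = 2, nRewired = 4L, nDE = 25L, seed = 3L)
  de <- computeDETable(sim$experiment)
  tight <- poolGenes(selectCandidates(sim$experiment, de,
                                      statCut = 0.01, lfcCut = 0.8))
  looseStat <- poolGenes(selectCandidates(sim$experiment, de,
                                          statCut = 0.1, lfcCut = 0.8))
  looseLfc <- poolGenes(selectCandidates(sim$experiment, de,
                                         statCut = 0.01, lfcCut = 0.2))
  expect_true(all(tight %in% looseStat))
  expect_true(all(tight %in% looseLfc))
})
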