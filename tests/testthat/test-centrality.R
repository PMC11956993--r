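test_that("betweenness matches closed forms on path and star graphs", {
  p <- makeNet(c("a", "b", "c"), c("a", "b"), c("b", "c"),
               distance = c(0.5, 0.5))
  expect_equal(weightedBetweenness(p),
               c(a = 0, b = 1, c = 0))
  st <- makeNet(as.character(0:5), rep("0", 5), as.character(1:5),
                distance = rep(0.4, 5))
  bw <- weightedBetweenness(st)
  expect_equal(bw[["0"]], 10)  # C(5,2)
  expect_equal(unname(bw[as.character(1:5)]), rep(0, 5))
  # normalized variant divides by (n-1)(n-2)/2
  expect_equal(weightedBetweenness(st, normalized = TRUE)[["0"]], 1)
})

test_that("betweenness splits credit across tied shortest paths", {
  # 4-cycle with equal distances: each s-t diagonal pair has two tied paths
  cy <- makeNet(letters[1:4], c("a", "b", "c", "d"), c("b", "c", "d", "a"),
                distance = rep(0.3, 4))
  expect_equal(weightedBetweenness(cy),
               c(a = 0.5, b = 0.5, c = 0.5, d = 0.5))
  # ties assembled from different floating-point sums are still detected:
  # a-d ties via b and c (0.2+0.4 = 0.4+0.2), b-c ties via a and d
  tie <- makeNet(letters[1:4], c("a", "b", "a", "c"), c("b", "d", "c", "d"),
                 distance = c(0.2, 0.4, 0.4, 0.2))
  expect_equal(weightedBetweenness(tie),
               c(a = 0.5, b = 0.5, c = 0.5, d = 0.5))
})

test_that("zero-distance edges are legal for shortest paths", {
  z <- makeNet(c("a", "b", "c"), c("a", "b"), c("b", "c"),
               distance = c(0, 0.5))
  expect_equal(weightedBetweenness(z), c(a = 0, b = 1, c = 0))
  # a negative distance cannot even enter a valid network object
  expect_error(makeNet(c("a", "b"), "a", "b", distance = -0.1))
  expect_error(dicenet:::.brandesBetweenness(2L, 0L, 1L, -0.1, FALSE),
               "negative")
})

test_that("betweenness agrees with exhaustive path enumeration and igraph", {
  library(igraph)
  set.seed(101)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    g <- randomConnectedGraph(n)
    net <- makeNet(as.character(1:n), as.character(g$from),
                   as.character(g$to), distance = g$w)
    mine <- as.numeric(weightedBetweenness(net))
    expect_equal(mine, bruteBetweenness(n, g$from, g$to, g$w),
                 tolerance = 1e-9)
    ig <- graph_from_edgelist(cbind(g$from, g$to), directed = FALSE)
    expect_equal(mine, as.numeric(betweenness(ig, weights = g$w)),
                 tolerance = 1e-9)
  }
})

test_that("eigenvector centrality matches symmetry and spectral closed forms", {
  tri <- makeNet(c("a", "b", "c"), c("a", "a", "b"), c("b", "c", "c"),
                 cc = rep(0.5, 3))
  expect_equal(unname(eigenvectorCentrality(tri)), rep(1, 3),
               tolerance = 1e-9)
  for (n in c(4, 9, 16)) {
    st <- makeNet(as.character(0:n), rep("0", n), as.character(1:n),
                  cc = rep(0.6, n))
    ev <- eigenvectorCentrality(st)
    expect_equal(ev[["0"]], 1)
    expect_equal(unname(ev[as.character(1:n)]), rep(1 / sqrt(n), n),
                 tolerance = 1e-8)
  }
})

test_that("power iteration agrees with a dense eigen-decomposition", {
  set.seed(103)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    gg <- randomGappedGraph(n)
    g <- gg$g; aff <- gg$aff; A <- gg$A
    net <- makeNet(as.character(1:n), as.character(g$from),
                   as.character(g$to), cc = aff)
    ev <- as.numeric(eigenvectorCentrality(net))
    ref <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    expect_lt(angleBetween(ev, ref), 1e-8)
    # eigen-equation residual
    lambda <- eigen(A, symmetric = TRUE)$values[1]
    expect_lt(max(abs(A %*% ev - lambda * ev)), 1e-7)
  }
  none <- makeNet(c("a", "b"), "a", "b", cc = 0)
  expect_error(eigenvectorCentrality(none), "zero")
})

test_that("both centralities are permutation-equivariant", {
  set.seed(107)
  g <- randomConnectedGraph(10)
  nodes <- as.character(1:10)
  net <- makeNet(nodes, as.character(g$from), as.character(g$to),
                 cc = 1 - g$w)
  perm <- sample(nodes)
  net2 <- makeNet(perm, as.character(g$from), as.character(g$to),
                  cc = 1 - g$w)
  expect_equal(weightedBetweenness(net)[perm], weightedBetweenness(net2)[perm])
  expect_equal(eigenvectorCentrality(net)[perm],
               eigenvectorCentrality(net2)[perm], tolerance = 1e-9)
})

test_that("centrality deltas are exact, symmetric and gene-set checked", {
  tA <- data.frame(gene = c("a", "b", "c"), betweenness = c(1, 2, 0),
                   eigen = c(1, 0.5, 0.2))
  tB <- data.frame(gene = c("c", "a", "b"), betweenness = c(3, 1, 0),
                   eigen = c(0.1, 1, 0.9))
  ct <- centralityDeltas(tA, tB, conditions = c("N", "T"))
  t <- centralities(ct)
  expect_equal(t$abs_delta_betweenness, abs(t$betweenness_B - t$betweenness_A))
  expect_equal(t$abs_delta_eigen[t$gene == "c"], 0.1)
  # swap symmetry
  ct2 <- centralityDeltas(tB, tA, conditions = c("T", "N"))
  t2 <- centralities(ct2)[match(t$gene, centralities(ct2)$gene), ]
  expect_equal(t$abs_delta_betweenness, t2$abs_delta_betweenness)
  expect_equal(t$abs_delta_eigen, t2$abs_delta_eigen)
  # identical tables give all-zero deltas
  ct0 <- centralityDeltas(tA, tA)
  expect_equal(centralities(ct0)$abs_delta_betweenness, rep(0, 3))
  err <- expect_error(centralityDeltas(tA, tB[1:2, ]))
  expect_match(conditionMessage(err), "b|c")
})

test_that("perturbing one edge only moves deltas where structure changes", {
  # path a-b-c-d; lengthening edge c-d changes paths through c but not a-b
  nodes <- letters[1:4]
  nA <- makeNet(nodes, c("a", "b", "c"), c("b", "c", "d"),
                distance = c(0.2, 0.2, 0.2))
  nB <- makeNet(nodes, c("a", "b", "c"), c("b", "c", "d"),
                distance = c(0.2, 0.2, 0.9))
  ct <- centralityDeltas(
    data.frame(gene = nodes,
               betweenness = as.numeric(weightedBetweenness(nA)),
               eigen = as.numeric(eigenvectorCentrality(nA))),
    data.frame(gene = nodes,
               betweenness = as.numeric(weightedBetweenness(nB)),
               eigen = as.numeric(eigenvectorCentrality(nB))))
  t <- centralities(ct)
  # betweenness counts are path counts: unchanged here (same topology),
  # but the eigenvector shifts for every node connected to the change
  expect_equal(t$abs_delta_betweenness, rep(0, 4))
  expect_gt(t$abs_delta_eigen[t$gene == "d"], 0)
})
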