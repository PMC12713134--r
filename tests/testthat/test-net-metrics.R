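# The six network measures against hand computations, closed forms, and
# independent brute-force / igraph oracles.

directedCycle <- function(n, w = 1) {
  makeNet(0:(n - 1), c(1:(n - 1), 0), rep(w, n))
}

biStar <- function(leaves) {
  makeNet(c(rep(0, leaves), seq_len(leaves)),
          c(seq_len(leaves), rep(0, leaves)), 1)
}

completeDigraph <- function(n) {
  pr <- expand.grid(a = 0:(n - 1), b = 0:(n - 1))
  pr <- pr[pr$a != pr$b, ]
  makeNet(pr$a, pr$b, 1)
}

test_that("strength sums incident weights by direction", {
  net <- makeNet(c(2, 4), c(4, 2), c(20, 3))
  expect_equal(strength(net, 2), 23)
  expect_equal(strength(net, 2, "out"), 20)
  expect_equal(strength(net, 2, "in"), 3)
  iso <- makeNet(0, 1, 2, nodes = 0:2)
  expect_equal(strength(iso, 2), 0)
  expect_error(strength(net, 99), "unknown node")
})

test_that("average neighbor degree matches hand computations", {
  # bidirectional star, 3 leaves: center (1/6)(3 * 2 * 2) = 2
  st <- biStar(3)
  expect_equal(averageNeighborDegree(st, 0), 2)
  # 2-node single edge weight 5: both endpoints (1/5)(5 * 1) = 1
  tw <- makeNet(0, 1, 5)
  expect_equal(averageNeighborDegree(tw, 0), 1)
  expect_equal(averageNeighborDegree(tw, 1), 1)
  # weight-1 directed cycle: identical value at every node
  vals <- averageNeighborDegree(directedCycle(5))
  expect_equal(unname(vals), rep(vals[[1]], 5))
  # isolated node has no defined value
  iso <- makeNet(0, 1, 1, nodes = 0:2)
  expect_true(is.na(averageNeighborDegree(iso, 2)))
})

test_that("average degree connectivity groups nodes by degree", {
  cyc <- directedCycle(4)
  adc <- averageDegreeConnectivity(cyc)
  expect_equal(nrow(adc), 1)
  expect_equal(adc$degree, 2)
  expect_equal(adc$value, averageNeighborDegree(cyc, 0))
  iso <- makeNet(0, 1, 1, nodes = 0:2)
  expect_false(0 %in% averageDegreeConnectivity(iso)$degree)
  # two-pass brute force on random graphs
  set.seed(61)
  for (i in 1:50) {
    net <- randomDigraph(sample(3:7, 1))
    adc <- averageDegreeConnectivity(net)
    annd <- averageNeighborDegree(net)
    ed <- edgeTable(net)
    k <- vapply(nodeIds(net), function(v)
      sum(ed$incoming == v) + sum(ed$outgoing == v), numeric(1))
    keep <- k > 0 & !is.na(annd)
    for (r in seq_len(nrow(adc))) {
      sel <- keep & k == adc$degree[r]
      expect_equal(adc$value[r], mean(annd[sel]))
    }
    expect_setequal(adc$degree, unique(k[keep]))
  }
})

test_that("distances on a unit directed 3-cycle enumerate by hand", {
  o <- allPairsDistances(directedCycle(3), "unweighted")
  offdiag <- o$dist[row(o$dist) != col(o$dist)]
  expect_true(all(offdiag %in% c(1, 2)))
  expect_equal(wienerIndex(directedCycle(3), "unweighted"), 9)
})

test_that("inverse weight mode scales distances reciprocally", {
  set.seed(77)
  net <- randomDigraph(6, 0.5)
  doubled <- new("BehaviorNetwork",
                 edges = transform(edgeTable(net), weight = weight * 2),
                 nodes = nodeIds(net), multigraph = FALSE)
  d1 <- allPairsDistances(net, "inverse")$dist
  d2 <- allPairsDistances(doubled, "inverse")$dist
  expect_equal(d2, d1 / 2)
  # raw mode scales proportionally
  r1 <- allPairsDistances(net, "raw")$dist
  r2 <- allPairsDistances(doubled, "raw")$dist
  expect_equal(r2, r1 * 2)
})

test_that("shortest-path machinery agrees with Floyd-Warshall and igraph", {
  set.seed(99)
  for (i in 1:120) {
    n <- sample(2:8, 1)
    net <- randomDigraph(n)
    mode <- sample(c("raw", "inverse", "unweighted"), 1)
    mine <- allPairsDistances(net, mode)
    fw <- fwOracle(net, mode)
    expect_equal(mine$dist, fw$dist)
    expect_equal(mine$sigma, fw$sigma)
    # independent library cross-check on distances
    ed <- edgeTable(net)
    if (nrow(ed)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(ed$incoming),
                   to = as.character(ed$outgoing)),
        directed = TRUE, vertices = as.character(nodeIds(net)))
      len <- switch(mode, raw = ed$weight, inverse = 1 / ed$weight,
                    unweighted = rep(1, nrow(ed)))
      dig <- igraph::distances(g, mode = "out", weights = len)
      expect_equal(unname(mine$dist),
                   unname(dig[rownames(mine$dist), colnames(mine$dist)]))
    }
  }
})

test_that("Wiener index and closeness obey directed-cycle closed forms", {
  for (n in c(3, 4, 6)) {
    cyc <- directedCycle(n)
    expect_equal(wienerIndex(cyc, "unweighted"), n^2 * (n - 1) / 2)
    cc <- closenessCentrality(cyc, weightMode = "unweighted")
    expect_equal(unname(cc), rep(2 / n, n))
  }
  expect_equal(closenessCentrality(directedCycle(4),
                                   weightMode = "unweighted")[["0"]], 0.5)
})

test_that("closeness handles complete graphs and unreachable nodes", {
  K4 <- completeDigraph(4)
  expect_equal(unname(closenessCentrality(K4, weightMode = "unweighted")),
               rep(1, 4))
  # node with no incoming edges has closeness 0
  chain <- makeNet(c(0, 1), c(1, 2), 1)
  expect_equal(closenessCentrality(chain, 0, "unweighted"), 0)
  # reachability scaling: on partially reachable graphs the value is
  # damped by (r - 1)/(n - 1)
  expect_equal(closenessCentrality(chain, 1, "unweighted"),
               (1 / 1) * (1 / 2))
})

test_that("closeness vitality matches hand computation and flags disconnections", {
  # bidirectional 3-path: W = 8, removing a leaf leaves W = 2
  p3 <- makeNet(c(0, 1, 1, 2), c(1, 0, 2, 1), 1)
  expect_equal(closenessVitality(p3, 0, "unweighted"), 6)
  # removing the middle node disconnects the leaves
  expect_identical(closenessVitality(p3, 1, "unweighted"), -Inf)
  expect_error(closenessVitality(p3, 9, "unweighted"), "unknown node")
})

test_that("vitality equals independent W(G) - W(G minus v) on random graphs", {
  set.seed(13)
  for (i in 1:40) {
    net <- randomDigraph(sample(3:6, 1))
    mode <- sample(c("raw", "inverse", "unweighted"), 1)
    for (v in nodeIds(net))
      expect_equal(closenessVitality(net, v, mode), fwVitality(net, v, mode))
  }
})

test_that("betweenness: star, complete graph, and enumeration oracle", {
  st <- biStar(4)
  cb <- betweennessCentrality(st, "unweighted")
  expect_equal(cb[["0"]], 12)
  expect_equal(unname(cb[-1]), rep(0, 4))
  expect_equal(unname(betweennessCentrality(completeDigraph(4),
                                            "unweighted")), rep(0, 4))
  # normalization by (n-1)(n-2)
  expect_equal(betweennessCentrality(st, "unweighted",
                                     normalized = TRUE)[["0"]], 1)
  set.seed(55)
  for (i in 1:60) {
    net <- randomDigraph(sample(2:5, 1))
    mode <- sample(c("raw", "inverse", "unweighted"), 1)
    expect_equal(betweennessCentrality(net, mode), enumBetweenness(net, mode))
  }
})

test_that("betweenness agrees with igraph on strongly structured graphs", {
  set.seed(14)
  for (i in 1:20) {
    net <- randomDigraph(sample(3:7, 1), 0.6)
    ed <- edgeTable(net)
    if (!nrow(ed)) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$incoming),
                 to = as.character(ed$outgoing)),
      directed = TRUE, vertices = as.character(nodeIds(net)))
    big <- igraph::betweenness(g, directed = TRUE, weights = ed$weight)
    mine <- betweennessCentrality(net, "raw")
    expect_equal(unname(mine[names(big)]), unname(big))
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(44)
  net <- randomDigraph(6, 0.5)
  perm <- sample(0:9, 6)  # new ids for nodes 0..5
  ed <- edgeTable(net)
  relabeled <- makeNet(perm[ed$incoming + 1], perm[ed$outgoing + 1],
                       ed$weight, nodes = sort(perm))
  for (v in nodeIds(net)) {
    expect_equal(strength(relabeled, perm[v + 1]), strength(net, v))
    expect_equal(betweennessCentrality(relabeled, "raw")[[as.character(perm[v + 1])]],
                 betweennessCentrality(net, "raw")[[as.character(v)]])
    expect_equal(closenessCentrality(relabeled, perm[v + 1], "raw"),
                 closenessCentrality(net, v, "raw"))
  }
})

test_that("metrics are identical on weighted and replicated representations", {
  set.seed(66)
  for (i in 1:10) {
    e <- randomValidSequence(60, 5)
    net <- buildNetwork(countTransitions(e))
    rep_net <- replicateEdges(net)
    expect_equal(strength(rep_net), strength(net))
    expect_equal(averageNeighborDegree(rep_net), averageNeighborDegree(net))
    expect_equal(allPairsDistances(rep_net, "raw")$dist,
                 allPairsDistances(net, "raw")$dist)
  }
})

test_that("distribution summaries: first quartile and robust max", {
  s <- summarizeDistribution(c(1, 2, 3, 4, 5))
  expect_equal(s$robust_max, 4)
  expect_equal(s$first_quartile, 2)
  s7 <- summarizeDistribution(c(7, 7, 7))
  expect_equal(s7$robust_max, 7)
  expect_equal(s7$first_quartile, 7)
  expect_equal(summarizeDistribution(c(0, 1, 2, 3))$first_quartile, 0.75)
  expect_true(is.na(summarizeDistribution(c(1, 2))$robust_max))
  expect_error(summarizeDistribution(numeric(0)), "empty")
})

test_that("nodeMetrics assembles all six measures coherently", {
  set.seed(3)
  net <- buildNetwork(countTransitions(randomValidSequence(80, 5)))
  nm <- nodeMetrics(net, "raw")
  expect_named(nm$nodes, c("node", "strength", "avg_neighbor_degree",
                           "closeness_vitality", "betweenness", "closeness"))
  expect_equal(nm$nodes$strength, unname(strength(net)))
  expect_equal(nm$nodes$betweenness,
               unname(betweennessCentrality(net, "raw")))
  expect_equal(nm$degree_connectivity, averageDegreeConnectivity(net))
})
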