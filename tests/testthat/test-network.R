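# Network thresholding, topology metrics, WiND, and power-law diagnosis.

simWithP <- function(s, p) {
  SimilarityMatrix(s, pvalues = p, modality = "test")
}

test_that("buildNetwork applies strict percentile and significance cuts", {
  ids <- sprintf("D%d", 1:6)
  s <- matrix(0, 6, 6, dimnames = list(ids, ids))
  vals <- seq(0.05, by = 0.06, length.out = 15)  # 15 distinct pair scores
  s[upper.tri(s)] <- vals
  s <- s + t(s); diag(s) <- 1
  p <- matrix(1, 6, 6, dimnames = list(ids, ids))
  # give the top two pairs small p
  top2 <- order(vals, decreasing = TRUE)[1:2]
  ut <- which(upper.tri(s), arr.ind = TRUE)
  for (k in top2) {
    p[ut[k, 1], ut[k, 2]] <- p[ut[k, 2], ut[k, 1]] <- 0.01
  }
  net <- buildNetwork(simWithP(s, p), percentile = 90, alpha = 0.05)
  # exhaustive oracle: score > quantile(vals, .9) AND p < .05
  cut <- quantile(vals, 0.9)
  surviving <- sum(vals > cut & seq_along(vals) %in% top2)
  expect_identical(igraph::ecount(networkGraph(net)), as.numeric(surviving))

  # all-equal scores: strict inequality kills every edge
  eq <- matrix(0.5, 6, 6, dimnames = list(ids, ids)); diag(eq) <- 1
  p0 <- matrix(0.001, 6, 6, dimnames = list(ids, ids)); diag(p0) <- 1
  net0 <- buildNetwork(simWithP(eq, p0))
  expect_identical(igraph::ecount(networkGraph(net0)), 0)
  # all p = 1: significance veto empties the network
  net1 <- buildNetwork(simWithP(s, matrix(1, 6, 6, dimnames = list(ids, ids))))
  expect_identical(igraph::ecount(networkGraph(net1)), 0)
  expect_setequal(isolatedDiseases(net1), ids)
  expect_error(buildNetwork(SimilarityMatrix(s, modality = "x")), "p-values")
  expect_error(buildNetwork(simWithP(s, p), percentile = 101), "percentile")
})

test_that("edge count is bounded by the percentile budget", {
  set.seed(8)
  for (k in 1:5) {
    n <- sample(10:30, 1)
    ids <- sprintf("D%03d", 1:n)
    s <- matrix(runif(n * n), n, n); s <- (s + t(s)) / 2; diag(s) <- 1
    p <- matrix(runif(n * n, 0, 0.04), n, n); p <- (p + t(p)) / 2; diag(p) <- 1
    dimnames(s) <- dimnames(p) <- list(ids, ids)
    net <- buildNetwork(simWithP(s, p))
    expect_lte(igraph::ecount(networkGraph(net)),
               ceiling(0.10 * choose(n, 2)))
  }
})

test_that("topology metrics match closed forms and a BFS recomputation", {
  mkNet <- function(g) {
    new("DiseaseNetwork", graph = g, modality = "t", percentile = 90,
        alpha = 0.05, isolated = character(0))
  }
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  t4 <- topologySummary(mkNet(k4))
  expect_equal(t4$density, 1)
  expect_equal(t4$transitivity, 1)
  expect_equal(t4$avgShortestPath, 1)
  expect_equal(t4$diameter, 1)
  expect_equal(t4$kCoreK, 3)

  path4 <- igraph::make_graph(~ A - B, B - C, C - D)
  tp <- topologySummary(mkNet(path4))
  expect_equal(tp$avgDegree, 1.5)
  expect_equal(tp$diameter, 3)
  expect_equal(tp$avgShortestPath, (1 + 1 + 1 + 2 + 2 + 3) / 6)

  # independent recomputation on random graphs: degrees from the adjacency
  # matrix, distances by hand-rolled BFS
  bfsDist <- function(adj, start) {
    n <- nrow(adj); d <- rep(Inf, n); d[start] <- 0; q <- start
    while (length(q)) {
      v <- q[[1]]; q <- q[-1]
      nb <- which(adj[v, ] > 0 & d > d[v] + 1)
      d[nb] <- d[v] + 1; q <- c(q, nb)
    }
    d
  }
  for (seed in 1:3) {
    net <- randomNetwork(50, 0.08, seed)
    ts <- topologySummary(net)
    adj <- as.matrix(igraph::as_adjacency_matrix(networkGraph(net)))
    expect_equal(ts$avgDegree, mean(rowSums(adj)))
    expect_equal(ts$density, sum(adj) / (nrow(adj) * (nrow(adj) - 1)))
    expect_equal(sort(ts$centrality$degree), sort(unname(rowSums(adj))))
    D <- t(sapply(seq_len(nrow(adj)), function(i) bfsDist(adj, i)))
    fin <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
    expect_equal(ts$avgShortestPath, mean(fin))
  }
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_error(topologySummary(mkNet(empty)), "no edges")
})

test_that("WiND matches hand enumeration and the all-member identity", {
  mkNet <- function(g) new("DiseaseNetwork", graph = g, modality = "t",
                           percentile = 90, alpha = 0.05,
                           isolated = character(0))
  k5 <- igraph::make_full_graph(5); igraph::V(k5)$name <- letters[1:5]
  expect_equal(wind(mkNet(k5), c("a", "c", "e"))$wind, 1)
  p3 <- igraph::make_graph(~ A - B, B - C)
  w <- wind(mkNet(p3))
  expect_equal(w$wind, (1 + 1 + 2) / 3)
  expect_identical(w$pairCount, 3L)
  expect_identical(w$directLinkCount, 2)
  # wind(ALL) == average shortest path length on random graphs
  for (seed in 1:50) {
    net <- randomNetwork(sample(15:40, 1), runif(1, 0.05, 0.2), seed)
    if (igraph::ecount(networkGraph(net)) == 0) next
    expect_equal(wind(net)$wind, topologySummary(net)$avgShortestPath,
                 tolerance = 1e-12)
  }
  # subset WiND in a connected graph is >= 1
  net <- randomNetwork(30, 0.15, 99)
  mem <- sample(igraph::V(networkGraph(net))$name, 8)
  expect_gte(wind(net, mem)$wind, 1)
  expect_error(wind(mkNet(p3), "A"), "at least two")
})

test_that("WiND ratios divide category by network closeness", {
  expect_equal(windRatio(1, 1), 1)
  expect_equal(round(windRatio(2.262, 2.420), 3), 0.935)
  expect_equal(round(windRatio(1.450, 2.375), 3), 0.611)
  expect_error(windRatio(1, 0), "positive")
})

test_that("power-law fitting recovers planted exponents and regimes", {
  set.seed(42)
  x <- rpowerlawDiscrete(2000, alpha = 2.5, xmin = 2)
  f <- powerlawClassify(x)
  expect_gte(f$alpha, 2.3); expect_lte(f$alpha, 2.7)
  expect_identical(f$classification, "scale-free")

  set.seed(7)
  pa <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  expect_identical(powerlawClassify(igraph::degree(pa))$classification,
                   "scale-free")
  set.seed(7)
  er <- igraph::sample_gnp(1000, 0.01)
  expect_identical(powerlawClassify(igraph::degree(er))$classification,
                   "random-like")
  expect_error(powerlawClassify(rep(3L, 50)), "constant")
  expect_error(powerlawClassify(1:5), "at least 10")
})
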