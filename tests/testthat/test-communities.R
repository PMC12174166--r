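# Clustering, partition agreement, robust consensus, enrichment.

test_that("Ward clustering recovers separable and planted structure", {
  # two perfect blocks
  blocks <- rep(1:2, each = 5)
  set.seed(1)
  m <- blockSimMatrix(10, blocks, noise = 0, base = 0, lift = 1)
  part <- wardClusters(SimilarityMatrix(m, modality = "t"), 2)
  expect_equal(adjustedRandIndex(partitionMembership(part),
                                 setNames(blocks, rownames(m))), 1)
  # 3 planted blocks with noise
  b3 <- rep(1:3, each = 10)
  set.seed(5)
  m3 <- blockSimMatrix(30, b3, noise = 0.05)
  p3 <- wardClusters(m3, 3)
  expect_gte(adjustedRandIndex(partitionMembership(p3),
                               setNames(b3, rownames(m3))), 0.9)
  # permuting rows permutes labels but not the partition
  ord <- sample(30)
  pPerm <- wardClusters(m3[ord, ord], 3)
  expect_equal(adjustedRandIndex(partitionMembership(p3),
                                 partitionMembership(pPerm)), 1)
  expect_error(wardClusters(m3[, 1:10], 3), "square")
  expect_error(wardClusters(m3, 1), ">= 2")
})

test_that("Leiden finds disconnected cliques and planted blocks", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- sprintf("D%02d", 1:10)
  net <- new("DiseaseNetwork", graph = g, modality = "t", percentile = 90,
             alpha = 0.05, isolated = character(0))
  part <- leidenClusters(net, seed = 1L)
  truth <- setNames(rep(1:2, each = 5), sprintf("D%02d", 1:10))
  expect_equal(adjustedRandIndex(partitionMembership(part), truth), 1)

  # planted 4-block graph
  set.seed(11)
  b <- rep(1:4, each = 10)
  pm <- matrix(0.02, 4, 4); diag(pm) <- 0.6
  sbm <- igraph::sample_sbm(40, pref.matrix = pm, block.sizes = rep(10, 4))
  igraph::V(sbm)$name <- sprintf("D%02d", 1:40)
  net4 <- new("DiseaseNetwork", graph = sbm, modality = "t", percentile = 90,
              alpha = 0.05, isolated = character(0))
  p4 <- leidenClusters(net4, seed = 2L)
  expect_gte(adjustedRandIndex(partitionMembership(p4),
                               setNames(b, sprintf("D%02d", 1:40))), 0.9)
  # community count is non-decreasing in resolution
  counts <- vapply(c(0.25, 0.5, 1, 2, 4), function(r)
    length(unique(partitionMembership(
      leidenClusters(net4, resolution = r, seed = 3L)))), integer(1))
  expect_true(all(diff(counts) >= 0))
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_error(leidenClusters(new("DiseaseNetwork", graph = empty,
                                  modality = "t", percentile = 90,
                                  alpha = 0.05, isolated = character(0))),
               "no edges")
})

test_that("adjusted Rand index matches hand values and chance behavior", {
  expect_equal(adjustedRandIndex(c(a = 1, b = 1, c = 2, d = 2),
                                 c(a = 1, b = 1, c = 2, d = 2)), 1)
  expect_equal(adjustedRandIndex(c(a = 1, b = 1, c = 2, d = 2),
                                 c(a = 1, b = 2, c = 1, d = 2)), -0.5)
  # chance correction: random labelings score ~0
  set.seed(21)
  ids <- sprintf("i%03d", 1:200)
  aris <- vapply(1:100, function(k) {
    adjustedRandIndex(setNames(sample(1:5, 200, TRUE), ids),
                      setNames(sample(1:5, 200, TRUE), ids))
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(adjustedRandIndex(c(a = 1), c(b = 1)), "disjoint")
  # independent cross-check against mclust on random partitions
  skip_if_not_installed("mclust")
  set.seed(4)
  for (k in 1:20) {
    p1 <- setNames(sample(1:4, 50, TRUE), sprintf("d%02d", 1:50))
    p2 <- setNames(sample(1:6, 50, TRUE), sprintf("d%02d", 1:50))
    expect_equal(adjustedRandIndex(p1, p2),
                 mclust::adjustedRandIndex(p1, p2), tolerance = 1e-12)
  }
})

test_that("Kendall consistency reproduces enumerated tau values", {
  expect_equal(kendallConsistency(list(a = c(1, 2, 3), b = c(1, 2, 3)))["a", "b"], 1)
  expect_equal(kendallConsistency(list(a = c(1, 2, 3), b = c(1, 3, 2)))["a", "b"],
               1 / 3, tolerance = 1e-12)
  expect_equal(kendallConsistency(list(a = c(1, 2, 3), b = c(3, 2, 1)))["a", "b"], -1)
  expect_error(kendallConsistency(list(a = 1, b = 2)), "at least 2")
})

test_that("robust communities are all-partition co-memberships", {
  ids <- sprintf("d%02d", 1:15)
  base <- setNames(rep(1:3, each = 5), ids)
  # all partitions identical: clusters of size >= 4 survive as-is
  rc <- robustCommunities(list(base, base, base), minSize = 4)
  expect_length(rc, 3)
  expect_setequal(unlist(lapply(rc, `[[`, "members")), ids)
  # one partition splits block 1: consensus shrinks to the intersections
  split <- base
  split[ids[1:2]] <- 9L
  rc2 <- robustCommunities(list(base, split), minSize = 2)
  sizes <- sort(vapply(rc2, `[[`, integer(1), "size"))
  expect_identical(sizes, c(2L, 3L, 5L, 5L))
  # brute-force co-membership oracle on random partitions
  set.seed(6)
  parts <- lapply(1:4, function(k) setNames(sample(1:3, 15, TRUE), ids))
  rc3 <- robustCommunities(parts, minSize = 2)
  coMember <- Reduce(`&`, lapply(parts, function(p) outer(p, p, `==`)))
  g <- igraph::graph_from_adjacency_matrix(coMember, mode = "undirected",
                                           diag = FALSE)
  comps <- igraph::components(g)
  bruteSizes <- sort(comps$csize[comps$csize >= 2])
  expect_identical(sort(vapply(rc3, `[[`, integer(1), "size")),
                   as.integer(bruteSizes))
  # order invariance
  rc3b <- robustCommunities(rev(parts), minSize = 2)
  expect_identical(lapply(rc3, `[[`, "members"),
                   lapply(rc3b, `[[`, "members"))
  # composition counts sum to community size
  cats <- setNames(sample(c("AD", "AID", "AA", "CA"), 15, TRUE), ids)
  rc4 <- robustCommunities(list(base, base), minSize = 4, categories = cats)
  for (com in rc4) expect_identical(sum(com$composition), com$size)
})

test_that("planted stable blocks survive consensus among noisy partitions", {
  # 3 stable blocks (6/5/4) + 5 noise diseases that wander across partitions
  ids <- sprintf("d%02d", 1:20)
  stable <- c(rep(1L, 6), rep(2L, 5), rep(3L, 4))
  set.seed(13)
  parts <- lapply(1:4, function(k) {
    lab <- c(stable, sample(1:3, 5, TRUE))
    setNames(lab, ids)
  })
  rc <- robustCommunities(parts, minSize = 4)
  core <- lapply(rc, function(com) intersect(com$members, ids[1:15]))
  expect_identical(sort(vapply(core, length, integer(1)),
                        decreasing = TRUE)[1:3], c(6L, 5L, 4L))
})

test_that("Fisher enrichment equals the hypergeometric tail with BH control", {
  # Table of 8 in-community (7 with feature) vs 61 outside (8 with feature)
  a <- 7; b <- 1; c_ <- 8; d <- 53
  p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                   alternative = "greater")$p.value
  # independent hypergeometric enumeration
  enum <- sum(vapply(a:(a + b), function(k)
    choose(a + c_, k) * choose(b + d, a + b - k) /
      choose(a + b + c_ + d, a + b), numeric(1)))
  expect_equal(p, enum, tolerance = 1e-12)

  # through the package surface
  ids <- sprintf("d%02d", 1:69)
  communities <- list(list(id = "C2", members = ids[1:8], size = 8L),
                      list(id = "Crest", members = ids[9:69], size = 61L))
  features <- setNames(rep(list(character(0)), 69), ids)
  for (i in c(1:7, 9:16)) features[[i]] <- "AID"
  for (i in 8:69) features[[i]] <- c(features[[i]], "other")
  enr <- featureEnrichment(communities, features)
  got <- enr[enr$community == "C2" & enr$feature == "AID", ]
  expect_equal(c(got$a, got$b, got$c, got$d), c(7, 1, 8, 53))
  expect_equal(got$p, enum, tolerance = 1e-12)
  # a feature present everywhere cannot be enriched
  all69 <- enr[enr$community == "Crest" & enr$feature == "other", ]
  # BH step-up by hand
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("a universally present feature is never enriched", {
  ids <- sprintf("d%02d", 1:12)
  communities <- list(list(id = "C1", members = ids[1:6], size = 6L),
                      list(id = "C2", members = ids[7:12], size = 6L))
  features <- setNames(rep(list("ubiquitous"), 12), ids)
  enr <- featureEnrichment(communities, features)
  expect_true(all(enr$p == 1))
})
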