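# Annotation profiles, FunSimAvg aggregation, weighted / cellular / drug
# similarity variants.

test_that("buildProfile maps, max-merges duplicates, and keeps topK terms", {
  # two genes on one term keep the larger weight
  p <- buildProfile("d1", "genetic",
                    data.frame(item = c("g1", "g2"), weight = c(0.4, 0.9)),
                    mapping = data.frame(item = c("g1", "g2"),
                                         term = c("T:1", "T:1")))
  expect_identical(p$term, "T:1")
  expect_identical(p$weight, 0.9)
  # topK retains the largest weights, ties by term id
  items <- data.frame(item = sprintf("g%02d", 1:30), weight = 30:1 / 30)
  map <- data.frame(item = items$item, term = sprintf("T:%02d", 1:30))
  p30 <- buildProfile("d2", "transcriptomic", items, map, topK = 20)
  expect_identical(nrow(p30), 20L)
  expect_setequal(p30$term, sprintf("T:%02d", 1:20))
  # unweighted character input gets weight 1 and all terms
  p2 <- buildProfile("d3", "genetic", c("T:1", "T:2"))
  expect_identical(p2$weight, c(1, 1))
  # unmappable disease yields an empty profile with a message
  expect_message(
    e <- buildProfile("d4", "genetic", "gX",
                      mapping = data.frame(item = "gY", term = "T:9")),
    "empty")
  expect_identical(nrow(e), 0L)
})

test_that("funSimAvg reproduces hand-computed best-match averages", {
  S <- matrix(c(0.5, 0.9), nrow = 1, dimnames = list("a", c("b", "c")))
  expect_equal(funSimAvg("a", c("b", "c"), S), 0.8, tolerance = 1e-12)
  # identical sets under identity term similarity
  I3 <- diag(3); dimnames(I3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(funSimAvg(c("x", "y", "z"), c("x", "y", "z"), I3), 1)
  expect_error(funSimAvg(character(0), "b", S), "non-empty")
})

test_that("funSimAvg is symmetric on random weighted set pairs", {
  set.seed(3)
  terms <- sprintf("T:%02d", 1:15)
  S <- matrix(runif(225), 15, 15, dimnames = list(terms, terms))
  S <- (S + t(S)) / 2; diag(S) <- 1
  for (k in 1:100) {
    t1 <- data.frame(term = sample(terms, sample(2:6, 1)),
                     weight = runif(1))
    t1$weight <- runif(nrow(t1))
    t2 <- data.frame(term = sample(terms, sample(2:6, 1)),
                     weight = runif(1))
    t2$weight <- runif(nrow(t2))
    w <- k %% 2 == 0
    expect_equal(funSimAvg(t1, t2, S, weighted = w),
                 funSimAvg(t2, t1, S, weighted = w), tolerance = 1e-12)
  }
})

test_that("pairwiseOADS equals brute-force per-pair evaluation", {
  sc <- syntheticScenario(nDiseases = 10L, kCommunities = 2L, nTerms = 80L)
  gen <- genAnnotations(sc)
  pr <- gen$profiles$genetic
  m <- simScores(pairwiseOADS(pr, gen$dag))
  expect_identical(unname(diag(m)), rep(1, 10))
  expect_lt(max(abs(m - t(m))), 1e-12)
  TS <- termSimilarityMatrix(gen$dag,
                             unique(unlist(lapply(pr, `[[`, "term"))))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(m[i, j], naiveBMA(pr[[i]]$term, pr[[j]]$term, TS),
                 tolerance = 1e-12)
  }
  # identical profiles score exactly 1
  two <- list(a = pr[[1]], b = pr[[1]])
  expect_equal(simScores(pairwiseOADS(two, gen$dag))["a", "b"], 1)
  expect_error(pairwiseOADS(pr[1], gen$dag), "at least two")
})

test_that("diseases sharing only the ontology root keep a positive floor", {
  dag <- siblingDag()
  m <- simScores(pairwiseOADS(list(d1 = data.frame(term = "A", weight = 1),
                                   d2 = data.frame(term = "B", weight = 1)),
                              dag))
  expect_equal(m["d1", "d2"], 1.6 / 3.6, tolerance = 1e-10)
  expect_gt(m["d1", "d2"], 0)
})

test_that("weighted FunSimAvg reduces to unweighted at uniform weights and
           ignores zero-weight terms", {
  sc <- syntheticScenario(nDiseases = 8L, kCommunities = 2L, nTerms = 60L)
  gen <- genAnnotations(sc)
  pr <- gen$profiles$genetic
  base <- simScores(pairwiseOADS(pr, gen$dag))
  uni <- lapply(pr, function(p) { p$weight <- rep(0.37, nrow(p)); p })
  expect_lt(max(abs(simScores(pairwiseOADS(uni, gen$dag, weighted = TRUE)) -
                    base)), 1e-12)
  # scale invariance: halving one disease's weights changes nothing
  wpr <- lapply(pr, function(p) { p$weight <- seq_len(nrow(p)); p })
  w1 <- simScores(dcWeightedOADS(wpr, gen$dag))
  wpr2 <- wpr
  wpr2[[1]]$weight <- wpr2[[1]]$weight / 2
  expect_lt(max(abs(simScores(dcWeightedOADS(wpr2, gen$dag)) - w1)), 1e-12)
  # zero-weight terms contribute nothing under geometric coupling
  dag <- makeDag(c("[Term]", "id: R", "name: r", "",
                   "[Term]", "id: A", "name: a", "is_a: R", "",
                   "[Term]", "id: B", "name: b", "is_a: R", "",
                   "[Term]", "id: C", "name: c", "is_a: R"))
  p1 <- data.frame(term = c("A", "B"), weight = c(1, 0))
  p2 <- data.frame(term = "A", weight = 1)
  m <- simScores(pairwiseOADS(list(x = p1, y = p2), dag, weighted = TRUE))
  # B has rescaled weight 0: x-side mean uses only A (perfect match)
  expect_equal(m["x", "y"], 1)
  expect_error(pairwiseOADS(list(x = data.frame(term = "A", weight = -1),
                                 y = p2), dag, weighted = TRUE), "negative")
})

test_that("cell proportion profiles normalize to the simplex", {
  prof <- cellProportionProfile("d1", c(T_cell = 50, B_cell = 50),
                                c(T_cell = "CL:1", B_cell = "CL:2"))
  expect_equal(prof$weight, c(0.5, 0.5))
  # scale invariance
  prof10 <- cellProportionProfile("d1", c(T_cell = 500, B_cell = 500),
                                  c(T_cell = "CL:1", B_cell = "CL:2"))
  expect_equal(prof$weight, prof10$weight)
  set.seed(4)
  g <- rgamma(6, shape = runif(6, 0.5, 3))
  counts <- setNames(g, sprintf("ct%d", 1:6))
  ids <- setNames(sprintf("CL:%d", 1:6), names(counts))
  p <- cellProportionProfile("d2", counts, ids)
  expect_lt(abs(sum(p$weight) - 1), 1e-9)
  expect_error(cellProportionProfile("d3", c(a = 0, b = 0), c(a = "CL:1", b = "CL:2")),
               "all-zero")
})

test_that("cell consistency ratios rank cell types by agreement", {
  p1 <- c(CD4 = 0.20, NK = 0.10, B = 0.30, Mono = 0.25, DC = 0.15)
  p2 <- c(CD4 = 0.16, NK = 0.40, B = 0.31, Mono = 0.05, DC = 0.08)
  expect_equal(cellConsistencyRatio(p1, p2, "CD4"), 1.25)
  expect_equal(cellConsistencyRatio(p1, p1, "NK"), 1)
  r <- cellConsistencyRatio(p1, p2)
  brute <- sort(vapply(names(p1), function(ct)
    max(p1[ct], p2[ct]) / min(p1[ct], p2[ct]), numeric(1)))
  expect_equal(r, brute)
  expect_error(cellConsistencyRatio(p1, p2[-1], "CD4x"), "absent")
})

test_that("tanimoto and drug-based similarity follow the BMA contract", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(1:5, 1:5), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_error(tanimoto(integer(0), integer(0)), "empty")

  ds <- matrix(c(1, 0.2, 0.6, 0.2, 1, 0.3, 0.6, 0.3, 1), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m <- drugBasedSimilarity(list(D1 = "x", D2 = c("y", "z")), ds)
  expect_equal(simScores(m)["D1", "D2"], 0.5 * (0.6 + 0.4))
  # identical drug sets -> 1
  m2 <- drugBasedSimilarity(list(A = c("x", "y"), B = c("x", "y")), ds)
  expect_equal(simScores(m2)["A", "B"], 1)
  # fingerprint route equals matrix route built from the same bits
  fps <- list(x = c(1, 2, 3), y = c(2, 3, 4), z = c(1, 5))
  drugs <- names(fps)
  tm <- outer(drugs, drugs, Vectorize(function(a, b) tanimoto(fps[[a]], fps[[b]])))
  dimnames(tm) <- list(drugs, drugs)
  sets <- list(D1 = c("x", "z"), D2 = "y", D3 = c("y", "z"), D4 = "x",
               D5 = c("x", "y", "z"), D6 = "z")
  mf <- drugBasedSimilarity(sets, fps)
  mm <- drugBasedSimilarity(sets, tm)
  expect_equal(simScores(mf), simScores(mm), tolerance = 1e-12)
  # brute force per pair
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(simScores(mf)[i, j],
                 naiveBMA(sets[[i]], sets[[j]], tm), tolerance = 1e-12)
  }
  expect_error(drugBasedSimilarity(list(D1 = character(0), D2 = "x"), ds),
               "at least one drug")
  expect_error(drugBasedSimilarity(list(D1 = "q", D2 = "x"), ds), "missing")
})

test_that("modality similarity means follow the planted pool tightness", {
  # default scenario: transcriptomic pools tightest, genetic most diffuse
  gen <- genAnnotations(syntheticScenario(seed = 2L))
  dag <- gen$dag
  off <- function(m) mean(m[upper.tri(m)])
  mTrans <- off(simScores(dcWeightedOADS(gen$profiles$transcriptomic, dag)))
  mPhe <- off(simScores(pairwiseOADS(gen$profiles$phenotypic, dag)))
  mGen <- off(simScores(pairwiseOADS(gen$profiles$genetic, dag)))
  expect_gt(mTrans, mPhe)
  expect_gt(mPhe, mGen)
})
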