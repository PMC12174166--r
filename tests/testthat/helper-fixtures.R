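# Shared fixtures and independent oracles used across the suite.

# Write an OBO file from stanza lines and load it.
makeDag <- function(lines, edgeWeights = c(is_a = 0.8, part_of = 0.6)) {
  f <- tempfile(fileext = ".obo")
  writeLines(lines, f)
  loadOntology(f, edgeWeights = edgeWeights)
}

# chain R <- A <- B (is_a)
chainDag <- function() {
  makeDag(c("[Term]", "id: R", "name: root", "",
            "[Term]", "id: A", "name: a", "is_a: R", "",
            "[Term]", "id: B", "name: b", "is_a: A"))
}

# siblings A, B under root R
siblingDag <- function() {
  makeDag(c("[Term]", "id: R", "name: root", "",
            "[Term]", "id: A", "name: a", "is_a: R", "",
            "[Term]", "id: B", "name: b", "is_a: R"))
}

# Brute-force BMA oracle, independent of funSimAvg / the C++ kernel:
# plain double loop over explicit best matches.
naiveBMA <- function(terms1, terms2, S) {
  best1 <- vapply(terms1, function(a) max(S[a, terms2]), numeric(1))
  best2 <- vapply(terms2, function(b) max(S[terms1, b]), numeric(1))
  (mean(best1) + mean(best2)) / 2
}

# Kruskal MST total weight via union-find (independent of the Prim path).
kruskalTotal <- function(edges) {
  edges <- edges[order(edges$dist, edges$from, edges$to), , drop = FALSE]
  nodes <- unique(c(edges$from, edges$to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  total <- 0
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[[i]]); rb <- find(edges$to[[i]])
    if (ra != rb) { parent[[ra]] <- rb; total <- total + edges$dist[[i]] }
  }
  total
}

# Random symmetric block similarity matrix used by SNF/clustering tests.
blockSimMatrix <- function(n, blocks, noise, base = 0.25, lift = 0.5) {
  ids <- sprintf("D%03d", seq_len(n))
  m <- base + lift * outer(blocks, blocks, "==") +
    matrix(rnorm(n * n, 0, noise), n, n)
  m <- pmin(pmax((m + t(m)) / 2, 0), 1)
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# Random connected-ish graph as a DiseaseNetwork (for wind/topology tests).
randomNetwork <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("D%03d", seq_len(n))
  deg <- igraph::degree(g)
  g <- igraph::induced_subgraph(g, deg > 0)
  new("DiseaseNetwork", graph = g, modality = "test", percentile = 90,
      alpha = 0.05, isolated = character(0))
}
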