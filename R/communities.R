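# Community detection (Ward hierarchical clustering, Leiden), partition
# agreement (ARI, Kendall tau), robust consensus communities and Fisher
# enrichment of community features.

#' Ward hierarchical clustering of a similarity matrix
#'
#' Agglomerative Ward linkage on the distance `1 - similarity`, cut into
#' `nClusters` groups.  Deterministic given the input; the induced partition
#' is invariant to row-order permutations of the matrix.
#'
#' @param sim a [SimilarityMatrix-class] (or square symmetric matrix with
#'   dimnames).
#' @param nClusters number of clusters (>= 2).
#' @return a [CommunityPartition-class] with method `"ward_hc"`.
#' @export
wardClusters <- function(sim, nClusters) {
  s <- if (is(sim, "SimilarityMatrix")) simScores(sim) else sim
  modality <- if (is(sim, "SimilarityMatrix")) modalityTag(sim) else
    "unspecified"
  if (!is.matrix(s) || nrow(s) != ncol(s))
    stop("similarity must be a square matrix")
  if (nClusters < 2) stop("nClusters must be >= 2")
  # order rows for label stability under input row permutations
  ord <- order(rownames(s))
  s <- s[ord, ord]
  hc <- hclust(as.dist(1 - s), method = "ward.D2")
  mem <- cutree(hc, k = nClusters)
  new("CommunityPartition", method = "ward_hc", modality = modality,
      membership = setNames(as.integer(mem), rownames(s)),
      parameters = list(n_clusters = nClusters))
}

#' Leiden community detection on a disease network
#'
#' Modularity-optimizing Leiden partition at the given resolution; the RNG
#' seed is fixed and recorded in the partition parameters.
#'
#' @param net a [DiseaseNetwork-class] with at least one edge.
#' @param resolution Leiden resolution parameter (study default 1.0).
#' @param seed integer RNG seed.
#' @param nIterations Leiden refinement iterations.
#' @return a [CommunityPartition-class] with method `"leiden"`.
#' @export
leidenClusters <- function(net, resolution = 1.0, seed = 1L,
                           nIterations = 5L) {
  g <- networkGraph(net)
  if (igraph::ecount(g) == 0L) stop("network has no edges")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = nIterations)
  new("CommunityPartition", method = "leiden", modality = modalityTag(net),
      membership = setNames(as.integer(igraph::membership(cl)),
                            igraph::V(g)$name),
      parameters = list(resolution = resolution, seed = seed))
}

.asMembership <- function(p) {
  if (is(p, "CommunityPartition")) return(partitionMembership(p))
  stopifnot(!is.null(names(p)))
  p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement in \[-1, 1\]; 1 for identical
#' partitions, ~0 for independent random labelings.
#'
#' @param p1,p2 [CommunityPartition-class] objects or named label vectors
#'   over the same disease set.
#' @return the ARI.
#' @export
adjustedRandIndex <- function(p1, p2) {
  m1 <- .asMembership(p1)
  m2 <- .asMembership(p2)
  shared <- intersect(names(m1), names(m2))
  if (!length(shared)) stop("partitions cover disjoint disease sets")
  a <- factor(m1[shared])
  b <- factor(m2[shared])
  tab <- table(a, b)
  n <- length(shared)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxIndex <- (sumA + sumB) / 2
  if (maxIndex == expected) return(0)  # both partitions trivial
  (sumij - expected) / (maxIndex - expected)
}

#' Kendall tau-b consistency of disease-pair rankings across modalities
#'
#' @param rankings named list of numeric vectors (similarity scores or ranks
#'   of the same disease pairs, in the same order) — one per modality; or a
#'   numeric matrix/data.frame with one column per modality.
#' @return symmetric matrix of Kendall tau-b coefficients.
#' @export
kendallConsistency <- function(rankings) {
  m <- if (is.list(rankings) && !is.data.frame(rankings))
    do.call(cbind, rankings) else as.matrix(rankings)
  if (nrow(m) < 2L) stop("need at least 2 shared disease pairs")
  cor(m, method = "kendall")
}

#' Robust consensus communities across partitions
#'
#' Two diseases are linked iff they share a cluster in EVERY supplied
#' partition; connected components of that co-clustering graph with at least
#' `minSize` members are the robust communities.  Output is invariant to the
#' order partitions are supplied.
#'
#' @param partitions list of >= 2 [CommunityPartition-class] objects (or
#'   named label vectors); only diseases covered by all partitions are used.
#' @param minSize minimal community size (study default 4).
#' @param categories optional named character vector disease -> category
#'   (e.g. AD/AID/CA/AA) for composition counts.
#' @param agreeAtLeast number of partitions that must agree for a
#'   co-membership link; defaults to all of them (the strictest rule).
#' @return list of communities, each a list with `id`, `members`, `size` and
#'   (when categories are given) `composition` counts summing to the size.
#' @export
robustCommunities <- function(partitions, minSize = 4L, categories = NULL,
                              agreeAtLeast = length(partitions)) {
  stopifnot(length(partitions) >= 2L)
  mems <- lapply(partitions, .asMembership)
  shared <- Reduce(intersect, lapply(mems, names))
  if (!length(shared)) stop("partitions cover disjoint disease sets")
  shared <- sort(shared)
  n <- length(shared)
  agree <- matrix(0L, n, n)
  for (m in mems) {
    lab <- m[shared]
    agree <- agree + outer(lab, lab, `==`)
  }
  adj <- agree >= agreeAtLeast
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- shared
  comps <- igraph::components(g)
  keep <- which(comps$csize >= minSize)
  out <- list()
  for (k in seq_along(keep)) {
    members <- sort(shared[comps$membership == keep[[k]]])
    com <- list(id = paste0("C", k), members = members,
                size = length(members))
    if (!is.null(categories)) {
      com$composition <- table(factor(categories[members],
                                      levels = unique(categories)))
    }
    out[[k]] <- com
  }
  # deterministic order: by decreasing size, then first member
  ord <- order(-vapply(out, `[[`, integer(1), "size"),
               vapply(out, function(c) c$members[[1L]], character(1)))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$id <- paste0("C", k)
  out
}

#' Feature enrichment within robust communities
#'
#' For each community and feature, builds the 2x2 table
#' (in-community with/without feature vs outside with/without, the universe
#' being all diseases assigned to robust communities), applies a one-sided
#' (greater) Fisher exact test, and Benjamini-Hochberg adjusts across the
#' features tested within each community.
#'
#' @param communities output of [robustCommunities()].
#' @param features named list disease id -> character vector of features
#'   (phenotype terms, pathways, categories, ...).
#' @param alpha significance threshold reported in the `enriched` column.
#' @return data.frame with columns `community`, `feature`, `a`, `b`, `c`,
#'   `d`, `p`, `p_adj`, `enriched`.
#' @export
featureEnrichment <- function(communities, features, alpha = 0.05) {
  universe <- unique(unlist(lapply(communities, `[[`, "members")))
  featUniverse <- unique(unlist(features[universe]))
  if (!length(featUniverse)) stop("no features cover the community members")
  hasFeat <- function(ids, f)
    vapply(ids, function(d) f %in% (features[[d]] %||% character(0)),
           logical(1))
  rows <- list()
  for (com in communities) {
    inside <- com$members
    outside <- setdiff(universe, inside)
    feats <- unique(unlist(features[inside]))
    if (!length(feats)) next
    res <- lapply(sort(feats), function(f) {
      a <- sum(hasFeat(inside, f)); b <- length(inside) - a
      c_ <- sum(hasFeat(outside, f)); d <- length(outside) - c_
      p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                       alternative = "greater")$p.value
      data.frame(community = com$id, feature = f, a = a, b = b, c = c_,
                 d = d, p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- p.adjust(res$p, method = "BH")
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  out$enriched <- out$p < alpha & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
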