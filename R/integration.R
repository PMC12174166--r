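# Multi-modal integration: similarity network fusion (SNF), benchmark
# correlation of similarity matrices, and minimum-spanning-tree disease
# trajectories (Prim's algorithm with deterministic tie-breaking).

# scaled-exponential affinity kernel on distance d = 1 - sim (Wang et al.
# SNF construction): per-pair bandwidth from the K-nearest-neighbor mean
# distances of the two nodes plus their own distance.
.snfAffinity <- function(sim, K, mu) {
  d <- 1 - sim
  diag(d) <- 0
  n <- nrow(d)
  knnMean <- vapply(seq_len(n), function(i) {
    mean(sort(d[i, -i])[seq_len(K)])
  }, numeric(1))
  Sig <- (outer(knnMean, knnMean, `+`) + d) / 3
  Sig[Sig <= .Machine$double.eps] <- .Machine$double.eps
  dnorm(d, 0, mu * Sig)
}

# row-stochastic full kernel, symmetrized
.snfNormalize <- function(W) {
  rs <- rowSums(W)
  rs[rs == 0] <- 1
  P <- W / rs
  (P + t(P)) / 2
}

# K-nearest-neighbor local kernel: keep the K largest entries per row
# (self included — the kernel diagonal is maximal), row-normalized
.snfLocal <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(W[i, ], decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Similarity network fusion of per-modality matrices
#'
#' Standard SNF cross-diffusion: each input similarity matrix is turned into
#' a scaled-exponential affinity kernel on the distance `1 - sim` (or used
#' directly as an affinity), row-normalized into a full kernel P and a
#' K-nearest-neighbor local kernel S, then updated for `t` rounds as
#' `P_v <- S_v %*% mean(other P) %*% t(S_v)` (re-normalized and symmetrized
#' each round).  The output is the symmetrized mean of the final kernels:
#' symmetric, non-negative, and invariant to the order of the inputs.
#'
#' @param matrices list of >= 2 [SimilarityMatrix-class] objects (or plain
#'   matrices) over the same disease set (same ids, any order).
#' @param K neighborhood size (study default 10; must satisfy `K < n`).
#' @param t number of fusion iterations (study default 20).
#' @param mu kernel bandwidth scale (default 0.5).
#' @param kernel `"scaled_exponential"` (default) to build affinities from
#'   distances, or `"direct"` to use the similarities as affinities.
#' @return a [SimilarityMatrix-class] with modality `"fused"`.
#' @export
snfFuse <- function(matrices, K = 10L, t = 20L, mu = 0.5,
                    kernel = c("scaled_exponential", "direct")) {
  kernel <- match.arg(kernel)
  stopifnot(length(matrices) >= 2L, t >= 1L)
  ms <- lapply(matrices, function(m)
    if (is(m, "SimilarityMatrix")) simScores(m) else m)
  ids <- rownames(ms[[1L]])
  n <- length(ids)
  if (K < 1L || K >= n) stop("K must satisfy 1 <= K < number of diseases")
  for (m in ms) {
    if (!setequal(rownames(m), ids) || nrow(m) != n)
      stop("all matrices must cover the same disease set")
  }
  ms <- lapply(ms, function(m) m[ids, ids])

  W <- lapply(ms, function(m) {
    if (kernel == "scaled_exponential") .snfAffinity(m, K, mu) else m
  })
  P <- lapply(W, .snfNormalize)
  S <- lapply(W, .snfLocal, K = K)
  V <- length(P)
  eye <- diag(n)
  for (iter in seq_len(t)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      others <- Reduce(`+`, P[-v]) / (V - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      # identity regularization keeps each node anchored to itself across
      # diffusion rounds (standard SNF stabilization)
      Q <- Q + eye
      Pnew[[v]] <- (Q + t(Q)) / 2
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / V
  rs <- rowSums(fused)
  fused <- fused / rs            # row sums 1 before final symmetrization
  fused <- (fused + t(fused) + eye) / 2
  fused <- fused / max(fused)    # monotone rescale into [0, 1]
  dimnames(fused) <- list(ids, ids)
  SimilarityMatrix(fused, modality = "fused")
}

#' Pearson correlation of two similarity matrices against each other
#'
#' Correlates the off-diagonal upper-triangle entries over the diseases
#' shared by the two matrices (at least three required).
#'
#' @param m1,m2 [SimilarityMatrix-class] objects or matrices with dimnames.
#' @return Pearson r.
#' @export
benchmarkCorrelation <- function(m1, m2) {
  a <- if (is(m1, "SimilarityMatrix")) simScores(m1) else m1
  b <- if (is(m2, "SimilarityMatrix")) simScores(m2) else m2
  shared <- sort(intersect(rownames(a), rownames(b)))
  if (length(shared) < 3L) stop("need at least 3 shared diseases")
  a <- a[shared, shared]
  b <- b[shared, shared]
  x <- a[upper.tri(a)]
  y <- b[upper.tri(b)]
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in one matrix")
  cor(x, y)
}

# Prim's algorithm on one component; edges is a data.frame(from, to, dist)
# restricted to the component's nodes.  Ties broken by (dist, from, to).
.primComponent <- function(nodes, edges) {
  inTree <- setNames(rep(FALSE, length(nodes)), nodes)
  start <- sort(nodes)[1L]
  inTree[start] <- TRUE
  picked <- list()
  while (sum(inTree) < length(nodes)) {
    cross <- edges[xor(inTree[edges$from], inTree[edges$to]), , drop = FALSE]
    cross <- cross[order(cross$dist, cross$from, cross$to), , drop = FALSE]
    e <- cross[1L, ]
    picked[[length(picked) + 1L]] <- e
    inTree[[if (inTree[[e$from]]) e$to else e$from]] <- TRUE
  }
  do.call(rbind, picked)
}

#' Minimum-spanning-tree disease trajectory
#'
#' Filters the similarity matrix to significant pairs (score strictly above
#' the percentile cut and p below `alpha`), converts the surviving
#' similarities to distances `1 - similarity`, and grows a minimum spanning
#' tree per connected component with Prim's algorithm (equal-weight edges
#' resolved by lexicographic disease-id pair, so the tree is deterministic).
#' A disconnected post-filter graph yields a spanning forest with the
#' component count reported.
#'
#' @param sim a [SimilarityMatrix-class] with p-values.
#' @param percentile percentile cut (study default 90).
#' @param alpha significance cut (study default 0.05).
#' @return data.frame of tree edges (`from`, `to`, `distance`, `similarity`,
#'   `component`), with attributes `nComponents` and `retained` (disease
#'   ids kept after filtering).
#' @export
buildMST <- function(sim, percentile = 90, alpha = 0.05) {
  net <- buildNetwork(sim, percentile = percentile, alpha = alpha)
  g <- networkGraph(net)
  if (igraph::vcount(g) < 2L)
    stop("fewer than two diseases retained after filtering")
  el <- igraph::as_data_frame(g, what = "edges")
  # canonical orientation for deterministic tie-breaks
  swap <- el$from > el$to
  tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
  el$dist <- 1 - el$similarity
  comps <- igraph::components(g)
  nodes <- igraph::V(g)$name
  out <- list()
  for (k in seq_len(comps$no)) {
    cn <- nodes[comps$membership == k]
    if (length(cn) < 2L) next
    ce <- el[el$from %in% cn & el$to %in% cn, , drop = FALSE]
    tree <- .primComponent(cn, ce)
    tree$component <- k
    out[[length(out) + 1L]] <- tree
  }
  res <- do.call(rbind, out)
  res <- data.frame(from = res$from, to = res$to, distance = res$dist,
                    similarity = res$similarity, component = res$component,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "nComponents") <- comps$no
  attr(res, "retained") <- nodes
  if (comps$no > 1L)
    message("post-filter graph has ", comps$no,
            " components; returning a spanning forest")
  res
}

#' Newick-like bracket export of an MST component
#'
#' Roots the tree at the lexicographically smallest disease id and emits a
#' bracket string with edge distances as branch lengths, for tree viewers.
#'
#' @param mst edge data.frame from [buildMST()].
#' @param component which component to export.
#' @return a single Newick string (terminated by `;`).
#' @export
mstToNewick <- function(mst, component = 1L) {
  sub <- mst[mst$component == component, , drop = FALSE]
  if (!nrow(sub)) stop("no edges in component ", component)
  nodes <- sort(unique(c(sub$from, sub$to)))
  adj <- lapply(setNames(nodes, nodes), function(n) {
    rows <- sub[sub$from == n | sub$to == n, , drop = FALSE]
    data.frame(other = ifelse(rows$from == n, rows$to, rows$from),
               dist = rows$distance, stringsAsFactors = FALSE)
  })
  visit <- function(node, parent) {
    nb <- adj[[node]]
    nb <- nb[nb$other != (parent %||% ""), , drop = FALSE]
    nb <- nb[order(nb$other), , drop = FALSE]
    if (!nrow(nb)) return(node)
    kids <- vapply(seq_len(nrow(nb)), function(i)
      paste0(visit(nb$other[[i]], node), ":", format(nb$dist[[i]])),
      character(1))
    paste0("(", paste(kids, collapse = ","), ")", node)
  }
  paste0(visit(nodes[[1L]], NULL), ";")
}
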