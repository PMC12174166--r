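#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @export
setGeneric("ontologyRoots", function(x) standardGeneric("ontologyRoots"))

#' @export
setGeneric("termParents", function(x, term) standardGeneric("termParents"))

#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @export
setGeneric("simScores", function(x) standardGeneric("simScores"))

#' @export
setGeneric("simPvalues", function(x) standardGeneric("simPvalues"))

#' @export
setGeneric("modalityTag", function(x) standardGeneric("modalityTag"))

#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @export
setGeneric("isolatedDiseases", function(x) standardGeneric("isolatedDiseases"))

#' @export
setGeneric("partitionMembership",
           function(x) standardGeneric("partitionMembership"))

# Central S4 containers: ontology DAG, similarity matrix, thresholded disease
# network, community partition.  Validity methods enforce the structural
# invariants the downstream algorithms rely on.

#' Ontology DAG
#'
#' A rooted directed acyclic graph of ontology terms with typed parent edges
#' (e.g. `is_a`, `part_of`) and per-relation semantic contribution factors in
#' (0, 1), as used by the Wang similarity method.
#'
#' @slot terms character vector of unique term ids (CURIE-style).
#' @slot termNames character vector of term labels, parallel to `terms`.
#' @slot parents named list (by term id); each element is a character vector
#'   of parent term ids (empty for roots).
#' @slot relations named list parallel to `parents`; relation kind per edge.
#' @slot edgeWeights named numeric; semantic contribution factor per relation
#'   kind, strictly in (0, 1).
#' @slot rootIds character; term ids with no parents.
#' @slot replacedBy named character; obsolete id -> replacement id map kept
#'   from parsing, used to remap annotations.
#'
#' @seealso [loadOntology()], [wangSimilarity()]
#' @export
setClass("OntologyDAG",
  slots = c(
    terms       = "character",
    termNames   = "character",
    parents     = "list",
    relations   = "list",
    edgeWeights = "numeric",
    rootIds     = "character",
    replacedBy  = "character"
  )
)

# Kahn topological sort over child->parent edges; NULL when a cycle exists,
# in which case one cycle member is reported via attr("cycleMember").
.topologicalOrder <- function(terms, parents) {
  n <- length(terms)
  idx <- seq_len(n)
  names(idx) <- terms
  nParents <- vapply(parents, length, integer(1))
  children <- vector("list", n)  # parent -> children indices
  for (i in idx) {
    for (p in parents[[i]]) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  # process parents first: reverse edges so we peel terms with no remaining
  # unprocessed parents
  remaining <- nParents
  queue <- idx[remaining == 0L]
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    return(structure(character(0),
                     cycleMember = terms[which(remaining > 0L)[1L]]))
  }
  terms[order]
}

setValidity("OntologyDAG", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term ids must be unique")
  if (length(object@termNames) != length(object@terms))
    msg <- c(msg, "termNames must parallel terms")
  if (!identical(names(object@parents), object@terms) ||
      !identical(names(object@relations), object@terms))
    msg <- c(msg, "parents/relations must be named by terms, in order")
  unknown <- setdiff(unique(unlist(object@parents)), object@terms)
  if (length(unknown))
    msg <- c(msg, paste0("parents reference unknown terms: ",
                         paste(head(unknown, 3), collapse = ", ")))
  if (length(object@edgeWeights) == 0 ||
      any(object@edgeWeights <= 0) || any(object@edgeWeights >= 1))
    msg <- c(msg, "edge contribution factors must lie strictly in (0, 1)")
  usedRel <- unique(unlist(object@relations))
  if (length(setdiff(usedRel, names(object@edgeWeights))))
    msg <- c(msg, "every relation kind needs an edge contribution factor")
  if (!length(msg)) {
    ord <- .topologicalOrder(object@terms, object@parents)
    if (length(ord) < length(object@terms))
      msg <- c(msg, paste0("ontology graph contains a cycle (involving term '",
                           attr(ord, "cycleMember"), "')"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OntologyDAG-class term ids.
#' @param x an `OntologyDAG`.
#' @export
setMethod("ontologyTerms", "OntologyDAG", function(x) x@terms)

#' @describeIn OntologyDAG-class root term ids (no parents).
#' @export
setMethod("ontologyRoots", "OntologyDAG", function(x) x@rootIds)

#' @describeIn OntologyDAG-class parents of one term, named by relation kind.
#' @param term a term id.
#' @export
setMethod("termParents", "OntologyDAG", function(x, term) {
  if (!term %in% x@terms)
    stop("unknown term id: ", term)
  setNames(x@parents[[term]], x@relations[[term]])
})

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG with", length(object@terms), "terms,",
      length(object@rootIds), "root(s)\n")
  cat("  relations:",
      paste(sprintf("%s=%.2f", names(object@edgeWeights),
                    object@edgeWeights), collapse = ", "), "\n")
})

#' Disease-disease similarity matrix
#'
#' Symmetric matrix of ontology-aware disease similarity scores in \[0, 1\],
#' optionally paired with a matrix of permutation p-values in (0, 1\].
#'
#' @slot scores symmetric numeric matrix with disease ids as dimnames.
#' @slot pvalues `NULL`, or a symmetric numeric matrix of the same shape.
#' @slot modality character tag, e.g. `"genetic"`, `"phenotypic"`, `"fused"`.
#'
#' @export
setClass("SimilarityMatrix",
  slots = c(scores = "matrix", pvalues = "ANY", modality = "character"))

setValidity("SimilarityMatrix", function(object) {
  s <- object@scores
  msg <- character(0)
  if (nrow(s) != ncol(s)) msg <- c(msg, "scores must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    msg <- c(msg, "scores needs identical row/col disease ids")
  if (anyNA(s) || any(!is.finite(s)))
    msg <- c(msg, "scores must be finite")
  else {
    if (max(abs(s - t(s))) > 1e-12)
      msg <- c(msg, "scores must be symmetric (tolerance 1e-12)")
    if (min(s) < -1e-12 || max(s) > 1 + 1e-12)
      msg <- c(msg, "scores must lie in [0, 1]")
  }
  p <- object@pvalues
  if (!is.null(p)) {
    if (!is.matrix(p) || !identical(dim(p), dim(s)))
      msg <- c(msg, "pvalues must match the score matrix shape")
    else if (anyNA(p) || any(p <= 0) || any(p > 1))
      msg <- c(msg, "pvalues must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param scores symmetric numeric matrix in \[0, 1\] with disease-id dimnames.
#' @param pvalues optional symmetric p-value matrix in (0, 1\].
#' @param modality modality tag.
#' @return a [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(scores, pvalues = NULL, modality = "unspecified") {
  scores <- (scores + t(scores)) / 2  # kill floating-point asymmetry
  new("SimilarityMatrix", scores = scores, pvalues = pvalues,
      modality = modality)
}

#' @describeIn SimilarityMatrix-class disease ids.
#' @param x a `SimilarityMatrix`.
#' @export
setMethod("diseaseIds", "SimilarityMatrix", function(x) rownames(x@scores))

#' @describeIn SimilarityMatrix-class the score matrix.
#' @export
setMethod("simScores", "SimilarityMatrix", function(x) x@scores)

#' @describeIn SimilarityMatrix-class the p-value matrix (or `NULL`).
#' @export
setMethod("simPvalues", "SimilarityMatrix", function(x) x@pvalues)

#' @describeIn SimilarityMatrix-class modality tag.
#' @export
setMethod("modalityTag", "SimilarityMatrix", function(x) x@modality)

setMethod("show", "SimilarityMatrix", function(object) {
  n <- nrow(object@scores)
  off <- object@scores[upper.tri(object@scores)]
  cat(sprintf("SimilarityMatrix (%s): %d diseases, mean off-diagonal %.3f%s\n",
              object@modality, n, if (length(off)) mean(off) else NA_real_,
              if (is.null(object@pvalues)) "" else ", with p-values"))
})

#' Thresholded disease association network
#'
#' Undirected graph of diseases whose pairwise similarity survived the
#' percentile and significance thresholds.  Isolated diseases are dropped
#' from the graph but recorded.
#'
#' @slot graph an `igraph` object; edges carry a `similarity` attribute.
#' @slot modality modality tag inherited from the similarity matrix.
#' @slot percentile percentile cut used (edges require score strictly above).
#' @slot alpha p-value cut used (edges require p strictly below).
#' @slot isolated disease ids scored but left without any surviving edge.
#'
#' @export
setClass("DiseaseNetwork",
  slots = c(graph = "ANY", modality = "character", percentile = "numeric",
            alpha = "numeric", isolated = "character"))

setValidity("DiseaseNetwork", function(object) {
  g <- object@graph
  msg <- character(0)
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g)) msg <- c(msg, "graph must not contain self-loops")
    if (igraph::any_multiple(g)) msg <- c(msg, "graph must be simple")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DiseaseNetwork-class the underlying igraph object.
#' @param x a `DiseaseNetwork`.
#' @export
setMethod("networkGraph", "DiseaseNetwork", function(x) x@graph)

#' @describeIn DiseaseNetwork-class disease ids retained as nodes.
#' @export
setMethod("diseaseIds", "DiseaseNetwork",
          function(x) igraph::V(x@graph)$name)

#' @describeIn DiseaseNetwork-class diseases dropped as isolated.
#' @export
setMethod("isolatedDiseases", "DiseaseNetwork", function(x) x@isolated)

#' @describeIn DiseaseNetwork-class modality tag.
#' @export
setMethod("modalityTag", "DiseaseNetwork", function(x) x@modality)

setMethod("show", "DiseaseNetwork", function(object) {
  g <- object@graph
  cat(sprintf(
    "DiseaseNetwork (%s): %d nodes, %d edges (score > P%g, p < %g; %d isolated)\n",
    object@modality, igraph::vcount(g), igraph::ecount(g),
    object@percentile, object@alpha, length(object@isolated)))
})

#' Community partition of a disease set
#'
#' @slot method `"ward_hc"` or `"leiden"`.
#' @slot modality modality tag.
#' @slot membership named integer vector: disease id -> cluster label.
#' @slot parameters list of method parameters (e.g. `n_clusters`,
#'   `resolution`, `seed`).
#'
#' @export
setClass("CommunityPartition",
  slots = c(method = "character", modality = "character",
            membership = "integer", parameters = "list"))

setValidity("CommunityPartition", function(object) {
  msg <- character(0)
  if (!object@method %in% c("ward_hc", "leiden"))
    msg <- c(msg, "method must be 'ward_hc' or 'leiden'")
  if (is.null(names(object@membership)) ||
      anyDuplicated(names(object@membership)) || anyNA(object@membership))
    msg <- c(msg, "membership must be a named integer vector, one label per disease")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityPartition-class named membership vector.
#' @param x a `CommunityPartition`.
#' @export
setMethod("partitionMembership", "CommunityPartition",
          function(x) x@membership)

#' @describeIn CommunityPartition-class disease ids covered.
#' @export
setMethod("diseaseIds", "CommunityPartition",
          function(x) names(x@membership))

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition (%s, %s): %d diseases in %d communities\n",
              object@method, object@modality, length(object@membership),
              length(unique(object@membership))))
})
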