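# Thresholded disease networks, topology summaries, and the within-network
# distance (WiND) statistic.

#' Build a thresholded disease association network
#'
#' An edge joins diseases i and j iff their similarity is strictly above the
#' given percentile of all off-diagonal (upper-triangle) scores AND its
#' permutation p-value is below `alpha`.  Diseases left without edges are
#' dropped from the graph but recorded as isolated.
#'
#' @param sim a [SimilarityMatrix-class] with p-values.
#' @param percentile percentile cut in (0, 100); study default 90.
#' @param alpha significance cut; study default 0.05.
#' @return a [DiseaseNetwork-class] (possibly with zero nodes).
#' @export
buildNetwork <- function(sim, percentile = 90, alpha = 0.05) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (is.null(simPvalues(sim)))
    stop("similarity matrix has no p-values; run oadsSignificance() first")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  s <- simScores(sim)
  p <- simPvalues(sim)
  ids <- diseaseIds(sim)
  ut <- upper.tri(s)
  cut <- as.numeric(quantile(s[ut], percentile / 100))
  keep <- which(ut & s > cut & p < alpha, arr.ind = TRUE)
  edges <- data.frame(from = ids[keep[, 1L]], to = ids[keep[, 2L]],
                      similarity = s[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new("DiseaseNetwork", graph = g, modality = modalityTag(sim),
      percentile = percentile, alpha = alpha,
      isolated = setdiff(ids, igraph::V(g)$name))
}

#' Topology summary of a disease network
#'
#' Node/edge counts, average degree, density, global transitivity, maximal
#' k-core (k and its size), average local clustering coefficient, average
#' shortest path length (over all connected pairs, so it coincides with the
#' all-member [wind()] by definition), diameter (largest connected component;
#' the component count is reported alongside), and per-node degree /
#' betweenness / closeness / eigenvector centralities.  Distances are hop
#' counts.
#'
#' @param net a [DiseaseNetwork-class] with at least one edge.
#' @return a list with the metrics above; `centrality` is a data.frame with
#'   one row per node.
#' @export
topologySummary <- function(net) {
  g <- networkGraph(net)
  if (igraph::ecount(g) == 0L) stop("network has no edges")
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  comps <- igraph::components(g)
  lcc <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  core <- igraph::coreness(g)
  kmax <- max(core)
  cent <- data.frame(
    disease_id = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, weights = NA)),
    closeness = suppressWarnings(
      as.numeric(igraph::closeness(g, weights = NA))),
    eigenvector = as.numeric(
      igraph::eigen_centrality(g, weights = NA)$vector),
    row.names = NULL, stringsAsFactors = FALSE)
  list(
    nNodes = n,
    nEdges = e,
    avgDegree = 2 * e / n,
    density = 2 * e / (n * (n - 1)),
    transitivity = igraph::transitivity(g, type = "global"),
    kCoreK = kmax,
    kCoreSize = sum(core == kmax),
    avgClustering = igraph::transitivity(g, type = "localaverage",
                                         isolates = "zero"),
    avgShortestPath = igraph::mean_distance(g, weights = NA),
    diameter = igraph::diameter(lcc, weights = NA),
    nComponents = comps$no,
    centrality = cent)
}

#' Within-network distance (WiND) of a disease subset
#'
#' The mean shortest-path length (hop count, measured in the full network)
#' over all connected pairs of the member set; with all nodes as members
#' this equals the network's average shortest path length.  Disconnected
#' member pairs are excluded from both the sum and the pair count.  The
#' number of direct (significant) links among members is also reported.
#'
#' @param net a [DiseaseNetwork-class].
#' @param members disease ids of the subset, or `NULL` for the whole network.
#' @return list with `wind`, `pairCount` (connected member pairs) and
#'   `directLinkCount` (edges with both ends in the member set).
#' @export
wind <- function(net, members = NULL) {
  g <- networkGraph(net)
  ids <- igraph::V(g)$name
  members <- if (is.null(members)) ids else intersect(members, ids)
  if (length(members) < 2L)
    stop("need at least two member diseases present in the network")
  d <- igraph::distances(g, v = members, to = members, weights = NA)
  vals <- d[upper.tri(d)]
  fin <- is.finite(vals)
  if (!any(fin)) stop("no connected member pair; WiND undefined")
  sub <- igraph::induced_subgraph(g, members)
  list(wind = sum(vals[fin]) / sum(fin),
       pairCount = sum(fin),
       directLinkCount = igraph::ecount(sub))
}

#' WiND ratio of a category subnetwork to the whole network
#'
#' `categoryWind / networkWind`; a ratio below 1 indicates that the category
#' clusters more tightly than the network as a whole.
#'
#' @param categoryWind WiND of the category's member set.
#' @param networkWind WiND of the full network (its average shortest path
#'   length); must be positive.
#' @return the ratio.
#' @export
windRatio <- function(categoryWind, networkWind) {
  if (!is.numeric(networkWind) || networkWind <= 0)
    stop("network WiND must be positive")
  categoryWind / networkWind
}

#' Export a disease network
#'
#' @param net a [DiseaseNetwork-class].
#' @param path output path.
#' @param format `"tsv"` (edge list `from<TAB>to<TAB>similarity`) or
#'   `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  g <- networkGraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
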