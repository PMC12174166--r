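# Permutation null model for disease similarity: the bipartite disease-term
# assignment is shuffled so that every disease keeps its term count and the
# global multiset of (term, weight) slots is preserved; similarities are
# recomputed on each shuffled dataset and empirical p-values use the add-one
# (Phipson-Smyth) estimator, so p is never exactly zero.

#' Shuffle disease-term assignments
#'
#' Permutes the pooled (term, weight) slots across diseases: each disease
#' keeps its term count, the global multiset of term occurrences is
#' preserved, and weights travel with their term slots.
#'
#' @param profiles named list of annotation profiles (data.frames with
#'   columns `term`, `weight`); at least two.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return named list of shuffled profiles with the same per-disease sizes.
#' @export
shuffleAnnotations <- function(profiles, seed = NULL) {
  profiles <- .asProfileList(profiles)
  if (length(profiles) < 2L) stop("need at least two profiles to shuffle")
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(profiles, nrow, integer(1))
  terms <- unlist(lapply(profiles, `[[`, "term"), use.names = FALSE)
  weights <- unlist(lapply(profiles, `[[`, "weight"), use.names = FALSE)
  perm <- sample.int(length(terms))
  terms <- terms[perm]
  weights <- weights[perm]
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  out <- Map(function(s, e) data.frame(term = terms[s:e],
                                       weight = weights[s:e],
                                       stringsAsFactors = FALSE),
             starts, ends)
  names(out) <- names(profiles)
  out
}

#' Empirical p-values from a permutation null
#'
#' For each disease pair, `p = (1 + #{null score >= observed}) / (1 + B)`
#' over `B` permutations of the annotation assignment, all pairs scored on
#' the same shared permutation stream.
#'
#' @param observed a [SimilarityMatrix-class] (or plain matrix) of observed
#'   scores.
#' @param profiles the annotation profiles that produced `observed`.
#' @param nullFun function mapping a (shuffled) profile list to a similarity
#'   matrix over the same diseases (a `SimilarityMatrix` or plain matrix).
#' @param nPermutations number of permutations (>= 1; the study default
#'   is 500).
#' @param seed integer seed for the shared permutation stream.
#' @return a [SimilarityMatrix-class] carrying the observed scores and the
#'   p-value matrix (diagonal fixed at 1).
#' @export
empiricalPvalues <- function(observed, profiles, nullFun,
                             nPermutations = 500L, seed = 1L) {
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  obs <- if (is(observed, "SimilarityMatrix")) simScores(observed) else observed
  modality <- if (is(observed, "SimilarityMatrix")) modalityTag(observed)
              else "unspecified"
  ge <- matrix(0L, nrow(obs), ncol(obs))
  set.seed(seed)
  for (b in seq_len(nPermutations)) {
    null <- nullFun(shuffleAnnotations(profiles))
    if (is(null, "SimilarityMatrix")) null <- simScores(null)
    ge <- ge + (null >= obs)
  }
  p <- (1 + ge) / (1 + nPermutations)
  diag(p) <- 1
  dimnames(p) <- dimnames(obs)
  out <- SimilarityMatrix(obs, pvalues = (p + t(p)) / 2, modality = modality)
  attr(out, "permutationSeed") <- seed
  attr(out, "nPermutations") <- nPermutations
  out
}

#' OADS with permutation significance
#'
#' Convenience wrapper computing the observed [pairwiseOADS()] matrix and its
#' empirical p-values on one shared permutation stream, reusing the Wang
#' term-similarity matrix across permutations (the term universe is
#' unchanged by shuffling, so recomputation is exact, only faster).
#'
#' @inheritParams pairwiseOADS
#' @param nPermutations number of annotation shuffles (study default 500).
#' @param seed integer seed for the permutation stream.
#' @return a [SimilarityMatrix-class] with scores and p-values.
#' @export
oadsSignificance <- function(profiles, dag, nPermutations = 500L, seed = 1L,
                             weighted = FALSE,
                             coupling = c("geometric", "arithmetic"),
                             modality = NULL) {
  coupling <- match.arg(coupling)
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  if (is.null(modality))
    modality <- attr(profiles[[1]], "modality") %||% "unspecified"
  prep <- .oadsPrepare(profiles, dag, weighted)
  geom <- coupling == "geometric"
  obs <- .bmaPairwise(prep$termIdx, prep$weights, prep$S, weighted, geom)

  counts <- vapply(prep$termIdx, length, integer(1))
  allIdx <- unlist(prep$termIdx, use.names = FALSE)
  allW <- unlist(prep$weights, use.names = FALSE)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  ge <- matrix(0L, nrow(obs), ncol(obs))
  set.seed(seed)
  for (b in seq_len(nPermutations)) {
    perm <- sample.int(length(allIdx))
    pi <- allIdx[perm]
    pw <- allW[perm]
    termIdx <- Map(function(s, e) pi[s:e], starts, ends)
    wts <- Map(function(s, e) pw[s:e], starts, ends)
    null <- .bmaPairwise(termIdx, wts, prep$S, weighted, geom)
    ge <- ge + (null >= obs)
  }
  p <- (1 + ge) / (1 + nPermutations)
  diag(p) <- 1
  dimnames(obs) <- dimnames(p) <- list(prep$ids, prep$ids)
  out <- SimilarityMatrix(obs, pvalues = (p + t(p)) / 2, modality = modality)
  attr(out, "excluded") <- prep$excluded
  attr(out, "permutationSeed") <- seed
  attr(out, "nPermutations") <- nPermutations
  out
}
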