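# Ontology-aware disease similarity (OADS): best-match-average (FunSimAvg)
# aggregation of a term-similarity matrix over two diseases' annotation
# profiles, with an optional dysregulation-weighted variant.

# Resolve a term-similarity source (matrix with dimnames, or function) into a
# lookup matrix over the needed terms.
.termsimMatrix <- function(termsim, terms1, terms2) {
  if (is.matrix(termsim)) {
    bad <- c(setdiff(terms1, rownames(termsim)),
             setdiff(terms2, colnames(termsim)))
    if (length(bad))
      stop("term(s) missing from similarity source: ",
           paste(head(unique(bad), 3), collapse = ", "))
    return(termsim[terms1, terms2, drop = FALSE])
  }
  stopifnot(is.function(termsim))
  outer(seq_along(terms1), seq_along(terms2),
        Vectorize(function(i, j) termsim(terms1[[i]], terms2[[j]])))
}

#' Best-match-average (FunSimAvg) similarity of two weighted term sets
#'
#' The unweighted score is the mean of (a) the average over `t1`'s terms of
#' their best match in `t2` and (b) the symmetric quantity.  In the weighted
#' variant, term weights are first min-max rescaled to \[0, 1\] within each
#' set (a constant set maps to all-ones), each term-pair similarity is
#' multiplied by a coupling `g(w_t, w_u)` (geometric `sqrt(w_t * w_u)` by
#' default, arithmetic `(w_t + w_u)/2` as an alternative) and the outer means
#' become weight-weighted means.  At uniform weights the weighted score
#' reduces exactly to the unweighted one.
#'
#' This is the reference (pure R) implementation; [pairwiseOADS()] computes
#' whole matrices through a compiled kernel and agrees with per-pair calls.
#'
#' @param t1,t2 non-empty data.frames with columns `term`, `weight`
#'   (or character vectors of terms, weight 1).
#' @param termsim term-similarity source: a matrix with term-id dimnames or a
#'   function `(a, b) -> score`.
#' @param weighted logical; apply the weighted variant.
#' @param coupling `"geometric"` or `"arithmetic"` weight coupling.
#' @return similarity in \[0, 1\].
#' @export
funSimAvg <- function(t1, t2, termsim, weighted = FALSE,
                      coupling = c("geometric", "arithmetic")) {
  coupling <- match.arg(coupling)
  if (!NROW(t1) || !NROW(t2)) stop("term sets must be non-empty")
  if (is.character(t1)) t1 <- data.frame(term = t1, weight = 1)
  if (is.character(t2)) t2 <- data.frame(term = t2, weight = 1)
  M <- .termsimMatrix(termsim, t1$term, t2$term)
  if (weighted) {
    w1 <- minMaxRescale(t1$weight)
    w2 <- minMaxRescale(t2$weight)
    G <- if (coupling == "geometric") sqrt(outer(w1, w2))
         else (outer(w1, w2, `+`)) / 2
    M <- M * G
    rowBest <- apply(M, 1, max)
    colBest <- apply(M, 2, max)
    0.5 * (sum(w1 * rowBest) / sum(w1) + sum(w2 * colBest) / sum(w2))
  } else {
    0.5 * (mean(apply(M, 1, max)) + mean(apply(M, 2, max)))
  }
}

# Shared driver behind pairwiseOADS / dcWeightedOADS / oadsSignificance.
# Returns list(ids, termIdx (0-based), weights (rescaled if weighted), S).
.oadsPrepare <- function(profiles, dag, weighted) {
  profiles <- .asProfileList(profiles)
  empty <- vapply(profiles, function(p) nrow(p) == 0L, logical(1))
  if (any(empty)) {
    message("excluding ", sum(empty), " disease(s) with empty profiles: ",
            paste(head(names(profiles)[empty], 5), collapse = ", "))
    profiles <- profiles[!empty]
  }
  if (length(profiles) < 2L)
    stop("need at least two diseases with non-empty profiles")
  if (weighted && any(vapply(profiles, function(p) any(p$weight < 0),
                             logical(1))))
    stop("negative term weights are invalid for the weighted variant")
  terms <- unique(unlist(lapply(profiles, `[[`, "term")))
  S <- termSimilarityMatrix(dag, terms)
  list(ids = names(profiles),
       termIdx = lapply(profiles, function(p)
         match(p$term, terms) - 1L),
       weights = lapply(profiles, function(p)
         if (weighted) minMaxRescale(p$weight) else p$weight),
       S = S,
       excluded = names(empty)[empty])
}

#' Pairwise ontology-aware disease similarity matrix
#'
#' Computes the symmetric FunSimAvg score for every disease pair over the
#' Wang term-similarity matrix of all annotated terms.  Diseases with empty
#' profiles are excluded (and recorded in the `excluded` attribute of the
#' result).  Self-similarity is 1 by definition.
#'
#' @param profiles named list (by disease id) of annotation profiles
#'   (data.frames with columns `term`, `weight`), all of one modality.
#' @param dag an [OntologyDAG-class] covering every annotated term.
#' @param weighted logical; apply the dysregulation-weighted FunSimAvg.
#' @param coupling weight coupling, see [funSimAvg()].
#' @param modality modality tag for the result (defaults to the first
#'   profile's `modality` attribute, else `"unspecified"`).
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseOADS <- function(profiles, dag, weighted = FALSE,
                         coupling = c("geometric", "arithmetic"),
                         modality = NULL) {
  coupling <- match.arg(coupling)
  if (is.null(modality))
    modality <- attr(profiles[[1]], "modality") %||% "unspecified"
  prep <- .oadsPrepare(profiles, dag, weighted)
  m <- .bmaPairwise(prep$termIdx, prep$weights, prep$S, weighted,
                    coupling == "geometric")
  dimnames(m) <- list(prep$ids, prep$ids)
  out <- SimilarityMatrix(m, modality = modality)
  attr(out, "excluded") <- prep$excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dysregulation-weighted transcriptomic disease similarity
#'
#' [pairwiseOADS()] with the weighted FunSimAvg variant: term weights are the
#' per-disease rescaled differential co-expression magnitudes (see
#' [normalizeDcWeights()]); zero-weight terms contribute nothing and the
#' score is invariant to rescaling one disease's weights.  With uniform
#' weights the result equals the unweighted matrix exactly.
#'
#' @inheritParams pairwiseOADS
#' @return a [SimilarityMatrix-class] with modality `"transcriptomic"`.
#' @export
dcWeightedOADS <- function(profiles, dag,
                           coupling = c("geometric", "arithmetic")) {
  pairwiseOADS(profiles, dag, weighted = TRUE, coupling = match.arg(coupling),
               modality = "transcriptomic")
}

#' Tanimoto coefficient of two fingerprint bit sets
#'
#' `|a ∩ b| / |a ∪ b|` over on-bit indices.
#'
#' @param a,b vectors of on-bit indices (integer or character); at least one
#'   must be non-empty.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("both fingerprints are empty")
  length(intersect(a, b)) / u
}

#' Drug-based disease similarity
#'
#' FunSimAvg over each disease's drug set, with drug-drug structural
#' similarity (e.g. fingerprint Tanimoto) in place of term similarity.
#'
#' @param drugSets named list (by disease id) of character vectors of drug
#'   ids; every disease needs at least one drug.
#' @param drugSim either a symmetric drug-drug similarity matrix with drug-id
#'   dimnames, or a named list of fingerprints (on-bit index vectors) from
#'   which the Tanimoto matrix is computed.
#' @return a [SimilarityMatrix-class] with modality `"drug"`.
#' @export
drugBasedSimilarity <- function(drugSets, drugSim) {
  stopifnot(is.list(drugSets), !is.null(names(drugSets)))
  if (any(vapply(drugSets, length, integer(1)) == 0L))
    stop("every disease needs at least one drug")
  drugs <- unique(unlist(drugSets))
  if (!is.matrix(drugSim)) {
    stopifnot(is.list(drugSim))
    missing <- setdiff(drugs, names(drugSim))
    if (length(missing))
      stop("drug(s) missing from fingerprint source: ",
           paste(missing, collapse = ", "))
    m <- matrix(1, length(drugs), length(drugs),
                dimnames = list(drugs, drugs))
    if (length(drugs) > 1) {
      for (i in seq_len(length(drugs) - 1L)) {
        for (j in (i + 1L):length(drugs)) {
          m[i, j] <- m[j, i] <- tanimoto(drugSim[[drugs[[i]]]],
                                         drugSim[[drugs[[j]]]])
        }
      }
    }
    drugSim <- m
  } else {
    missing <- setdiff(drugs, rownames(drugSim))
    if (length(missing))
      stop("drug(s) missing from similarity matrix: ",
           paste(missing, collapse = ", "))
  }
  ids <- names(drugSets)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- funSimAvg(drugSets[[i]], drugSets[[j]], drugSim)
      }
    }
  }
  SimilarityMatrix(m, modality = "drug")
}
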