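# Wang-method semantic similarity: a semantic contribution (S-value) of 1 is
# placed at the query term and decays by the relation's contribution factor
# per step toward the root, taking the maximum over multiple paths.  The
# similarity of two terms is the summed S-values of their common ancestors
# (each counted from both sides) over the two terms' total semantic values.

# S-values of `term` and all its ancestors as a named numeric vector.
# Queue-based relaxation over the DAG: monotone (factors < 1) so it converges.
termSValues <- function(dag, term) {
  if (!term %in% dag@terms) stop("unknown term id: ", term)
  s <- c(1)
  names(s) <- term
  queue <- term
  while (length(queue)) {
    x <- queue[[1L]]
    queue <- queue[-1L]
    ps <- dag@parents[[x]]
    if (!length(ps)) next
    ws <- dag@edgeWeights[dag@relations[[x]]]
    cand <- s[[x]] * ws
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      old <- s[p]
      if (is.na(old) || cand[[k]] > old) {
        s[p] <- cand[[k]]
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' @param dag an [OntologyDAG-class].
#' @param t1,t2 term ids present in `dag`.
#' @return similarity in \[0, 1\]; exactly 1 for `t1 == t2`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: R", "name: r", "",
#'   "[Term]", "id: A", "name: a", "is_a: R", "",
#'   "[Term]", "id: B", "name: b", "is_a: A"), obo)
#' dag <- loadOntology(obo)
#' wangSimilarity(dag, "A", "B")  # (1 + 0.8 + 0.8 + 0.64) / (1.8 + 2.44)
#' @export
wangSimilarity <- function(dag, t1, t2) {
  s1 <- termSValues(dag, t1)
  s2 <- termSValues(dag, t2)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Pairwise Wang similarity matrix between two term lists
#'
#' Entry `(i, j)` equals `wangSimilarity(dag, terms1[i], terms2[j])`; the
#' S-value vectors are computed once per distinct term.
#'
#' @param dag an [OntologyDAG-class].
#' @param terms1,terms2 non-empty character vectors of term ids
#'   (`terms2` defaults to `terms1`).
#' @return numeric matrix with `terms1`/`terms2` as dimnames.
#' @export
termSimilarityMatrix <- function(dag, terms1, terms2 = terms1) {
  if (!length(terms1) || !length(terms2))
    stop("term lists must be non-empty")
  all <- unique(c(terms1, terms2))
  bad <- setdiff(all, dag@terms)
  if (length(bad))
    stop("unknown term id(s): ", paste(head(bad, 3), collapse = ", "))
  sv <- lapply(all, termSValues, dag = dag)
  names(sv) <- all
  tot <- vapply(sv, sum, numeric(1))
  m <- matrix(NA_real_, length(terms1), length(terms2),
              dimnames = list(terms1, terms2))
  for (i in seq_along(terms1)) {
    s1 <- sv[[terms1[[i]]]]
    for (j in seq_along(terms2)) {
      if (terms1[[i]] == terms2[[j]]) { m[i, j] <- 1; next }
      s2 <- sv[[terms2[[j]]]]
      common <- intersect(names(s1), names(s2))
      m[i, j] <- sum(s1[common] + s2[common]) /
        (tot[[terms1[[i]]]] + tot[[terms2[[j]]]])
    }
  }
  m
}
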