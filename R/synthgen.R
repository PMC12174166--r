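# Synthetic-data generator: seeded ontologies with branch structure,
# multi-modal annotation profiles with planted disease communities, and
# multi-source classification labels.  Emits the same OBO/TSV formats the
# pipeline reads, so every stage is testable without external data.

#' Define a synthetic study scenario
#'
#' The defaults describe the reference synthetic study condition used
#' throughout the test suite: 5 planted communities of 20 diseases each,
#' community term pools drawn from distinct ontology subtrees, and a 5%
#' per-term noise rate.  Pool breadth and cross-community overlap differ by
#' modality: genetic pools are broad and mostly community-specific (sparse,
#' unevenly accumulated genetic-association knowledge), phenotypic pools
#' intermediate, and transcriptomic pools small and fully shared (dysregulated
#' genes concentrate in common immune pathway modules, with diseases differing
#' mainly in dysregulation magnitude).  By construction the mean similarity is
#' therefore ordered transcriptomic > phenotypic > genetic.
#'
#' @param seed integer master seed.
#' @param nTerms ontology size.
#' @param maxParents maximal number of parents per non-root term.
#' @param nDiseases number of diseases.
#' @param kCommunities number of planted communities (<= nDiseases).
#' @param poolOverlap fraction of each community's term pool shared with the
#'   other communities, in \[0, 1\]; either a scalar or a named per-modality
#'   vector.  The default keeps genetic pools mostly disease-specific
#'   (sparse, unevenly accumulated genetic knowledge) while transcriptomic
#'   dysregulation pools overlap heavily across communities (shared immune
#'   pathways), which concentrates transcriptomic similarity.
#' @param noise per-term probability of replacement by a random ontology
#'   term, in \[0, 1\].
#' @param sourceAgreement probability that a classification source labels a
#'   disease with its true polarity, in \[0, 1\] (wrong polarity and
#'   omission each take half the remainder).
#' @param modalities modalities to generate.
#' @param termsPerDisease named integer: annotated terms per disease per
#'   modality.
#' @param poolSize named integer: community term-pool size per modality.
#' @param nCellTypes number of cell types for the cellular modality.
#' @return a list of class `"syntheticScenario"`.
#' @export
syntheticScenario <- function(seed = 1L, nTerms = 300L, maxParents = 2L,
                              nDiseases = 100L, kCommunities = 5L,
                              poolOverlap = c(genetic = 0.1,
                                              transcriptomic = 1.0,
                                              phenotypic = 0.25),
                              noise = 0.05,
                              sourceAgreement = 0.8,
                              modalities = c("genetic", "transcriptomic",
                                             "phenotypic", "cellular"),
                              termsPerDisease = c(genetic = 8L,
                                                  transcriptomic = 6L,
                                                  phenotypic = 8L),
                              poolSize = c(genetic = 30L,
                                           transcriptomic = 7L,
                                           phenotypic = 18L),
                              nCellTypes = 8L) {
  stopifnot(all(poolOverlap >= 0), all(poolOverlap <= 1),
            noise >= 0, noise <= 1,
            sourceAgreement >= 0, sourceAgreement <= 1,
            kCommunities <= nDiseases, nTerms >= 2L)
  sc <- list(seed = as.integer(seed), nTerms = as.integer(nTerms),
             maxParents = as.integer(maxParents),
             nDiseases = as.integer(nDiseases),
             kCommunities = as.integer(kCommunities),
             poolOverlap = poolOverlap, noise = noise,
             sourceAgreement = sourceAgreement, modalities = modalities,
             termsPerDisease = termsPerDisease, poolSize = poolSize,
             nCellTypes = as.integer(nCellTypes))
  class(sc) <- "syntheticScenario"
  sc
}

#' Generate a random single-rooted ontology DAG
#'
#' Terms are created in order; each non-root term receives 1 to `maxParents`
#' parents drawn from earlier terms, guaranteeing acyclicity and a single
#' root.  With `nBranches` set, terms 2..(nBranches+1) become direct children
#' of the root and later terms attach within an assigned branch, giving the
#' DAG well-separated subtrees for planted community pools.  Fully
#' deterministic under a fixed seed.
#'
#' @param nTerms number of terms (>= 2).
#' @param maxParents maximal parents per non-root term (>= 1).
#' @param seed integer seed.
#' @param nBranches optional number of root-level branches.
#' @return an [OntologyDAG-class]; branch assignment (0 = root/branch head)
#'   is attached as attribute `"branch"` when `nBranches` is set.
#' @export
genOntology <- function(nTerms, maxParents = 2L, seed = 1L,
                        nBranches = NULL) {
  stopifnot(nTerms >= 2L)
  if (maxParents < 1L) stop("maxParents must be >= 1")
  set.seed(seed)
  ids <- sprintf("T:%06d", seq_len(nTerms))
  parents <- rep(list(character(0)), nTerms)
  relations <- rep(list(character(0)), nTerms)
  branch <- integer(nTerms)
  if (!is.null(nBranches)) {
    stopifnot(nBranches >= 1L, nTerms >= nBranches + 1L)
    for (i in seq_len(nBranches) + 1L) {
      parents[[i]] <- ids[[1L]]
      relations[[i]] <- "is_a"
      branch[[i]] <- i - 1L
    }
    startRest <- nBranches + 2L
    if (startRest <= nTerms) {
      for (i in startRest:nTerms) {
        b <- ((i - startRest) %% nBranches) + 1L
        branch[[i]] <- b
        candidates <- which(branch[seq_len(i - 1L)] == b)
        np <- sample.int(min(maxParents, length(candidates)), 1L)
        ps <- sort(sample(candidates, np))
        parents[[i]] <- ids[ps]
        relations[[i]] <- rep("is_a", np)
      }
    }
  } else {
    for (i in 2:nTerms) {
      np <- sample.int(min(maxParents, i - 1L), 1L)
      ps <- sort(sample.int(i - 1L, np))
      parents[[i]] <- ids[ps]
      relations[[i]] <- rep("is_a", np)
    }
  }
  names(parents) <- names(relations) <- ids
  dag <- new("OntologyDAG", terms = ids,
             termNames = paste("synthetic term", seq_len(nTerms)),
             parents = parents, relations = relations,
             edgeWeights = c(is_a = 0.8, part_of = 0.6),
             rootIds = ids[[1L]],
             replacedBy = setNames(character(0), character(0)))
  if (!is.null(nBranches)) attr(dag, "branch") <- setNames(branch, ids)
  dag
}

#' Generate multi-modal annotation profiles with planted communities
#'
#' Builds a branch-structured ontology, assigns each community a term pool
#' drawn from one branch subtree (with a `poolOverlap` fraction drawn from a
#' shared cross-branch pool), samples each disease's terms from its
#' community pool, and replaces each term with a uniformly random ontology
#' term with probability `noise`.  Transcriptomic weights are half-normal
#' dysregulation magnitudes, Z-scored per disease (emulating normalized dC
#' values) and rescaled by [normalizeDcWeights()]; cellular profiles are
#' per-community Dirichlet cell-type proportions over a fixed set of
#' cell-type terms.
#'
#' @param scenario a [syntheticScenario()].
#' @return list with `dag` (the ontology), `profiles` (per modality, a named
#'   list of annotation profiles), `labels` (named planted community per
#'   disease), `dcZ` (per-disease transcriptomic Z-scores, when generated).
#' @export
genAnnotations <- function(scenario) {
  stopifnot(inherits(scenario, "syntheticScenario"))
  sc <- scenario
  dag <- genOntology(sc$nTerms, sc$maxParents, seed = sc$seed,
                     nBranches = sc$kCommunities)
  branch <- attr(dag, "branch")
  set.seed(sc$seed + 1L)
  ids <- sprintf("D%03d", seq_len(sc$nDiseases))
  labels <- setNames(rep(seq_len(sc$kCommunities), length.out = sc$nDiseases),
                     ids)
  termModalities <- intersect(sc$modalities,
                              c("genetic", "transcriptomic", "phenotypic"))
  allTerms <- ontologyTerms(dag)
  profiles <- list()
  dcZ <- NULL

  for (m in termModalities) {
    ps <- sc$poolSize[[m]]
    tpd <- sc$termsPerDisease[[m]]
    ov <- if (length(sc$poolOverlap) > 1L) sc$poolOverlap[[m]]
          else sc$poolOverlap
    # shared cross-community pool and per-community branch pools
    shared <- sample(allTerms[branch > 0L], ps)
    pools <- lapply(seq_len(sc$kCommunities), function(c) {
      own <- allTerms[branch == c]
      nShared <- floor(ps * ov)
      pool <- unique(c(sample(own, min(ps - nShared, length(own))),
                       sample(shared, nShared)))
      if (length(pool) < tpd)
        stop("community pool smaller than termsPerDisease for modality ", m)
      pool
    })
    prof <- list()
    zrows <- list()
    for (d in ids) {
      pool <- pools[[labels[[d]]]]
      terms <- sample(pool, tpd)
      swap <- runif(tpd) < sc$noise
      if (any(swap)) terms[swap] <- sample(allTerms, sum(swap), replace = TRUE)
      terms <- unique(terms)
      if (m == "transcriptomic") {
        raw <- abs(rnorm(length(terms)))
        z <- if (length(raw) > 1L && sd(raw) > 0)
          (raw - mean(raw)) / sd(raw) else rep(0, length(raw))
        zrows[[d]] <- data.frame(disease_id = d, term = terms, z = z,
                                 stringsAsFactors = FALSE)
        w <- normalizeDcWeights(z)
      } else {
        w <- rep(1, length(terms))
      }
      ord <- order(terms)
      prof[[d]] <- .newProfile(d, m, terms[ord], w[ord])
    }
    profiles[[m]] <- prof
    if (m == "transcriptomic") dcZ <- do.call(rbind, zrows)
  }

  if ("cellular" %in% sc$modalities) {
    cellTerms <- sort(sample(allTerms[branch > 0L], sc$nCellTypes))
    alphas <- lapply(seq_len(sc$kCommunities), function(c) {
      a <- rep(0.5, sc$nCellTypes)
      fav <- sample.int(sc$nCellTypes, max(2L, sc$nCellTypes %/% 3L))
      a[fav] <- a[fav] + 4
      a
    })
    prof <- list()
    for (d in ids) {
      a <- alphas[[labels[[d]]]]
      g <- rgamma(sc$nCellTypes, shape = a)
      props <- g / sum(g)
      prof[[d]] <- .newProfile(d, "cellular", cellTerms, props)
    }
    profiles[["cellular"]] <- prof
  }

  list(dag = dag, profiles = profiles, labels = labels, dcZ = dcZ)
}

#' Generate multi-source AD/AID classification labels
#'
#' Each disease receives a true polarity (AD with probability 0.8, matching
#' the preponderance of autoimmune over autoinflammatory entries in curated
#' repositories); each of the seven classification sources labels it
#' correctly with probability `sourceAgreement`, with the wrong polarity
#' with probability `(1 - sourceAgreement)/2`, and otherwise omits it.
#'
#' @param scenario a [syntheticScenario()].
#' @param sources source names (default the seven study systems).
#' @return list with `labels` (data.frame `disease_id`, `source`, `label`)
#'   and `truth` (named true polarity per disease).
#' @export
genClassificationLabels <- function(scenario,
                                    sources = c("Mondo", "DO", "MeSH", "ICD",
                                                "AA", "ARI", "GAI")) {
  stopifnot(inherits(scenario, "syntheticScenario"))
  set.seed(scenario$seed + 2L)
  ids <- sprintf("D%03d", seq_len(scenario$nDiseases))
  truth <- setNames(sample(c("AD", "AID"), scenario$nDiseases,
                           replace = TRUE, prob = c(0.8, 0.2)), ids)
  a <- scenario$sourceAgreement
  rows <- list()
  for (d in ids) {
    for (s in sources) {
      u <- runif(1)
      lab <- if (u < a) truth[[d]]
             else if (u < a + (1 - a) / 2) setdiff(c("AD", "AID"), truth[[d]])
             else NA_character_
      if (!is.na(lab))
        rows[[length(rows) + 1L]] <- data.frame(
          disease_id = d, source = s, label = lab, stringsAsFactors = FALSE)
    }
  }
  list(labels = do.call(rbind, rows), truth = truth)
}

#' Write annotation profiles as TSV
#'
#' Layout: `disease_id<TAB>term_id<TAB>weight`.
#'
#' @param profiles named list of annotation profiles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(profiles, path) {
  profiles <- .asProfileList(profiles)
  rows <- do.call(rbind, lapply(names(profiles), function(d) {
    p <- profiles[[d]]
    if (!nrow(p)) return(NULL)
    data.frame(disease_id = d, term_id = p$term, weight = p$weight,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read annotation profiles from TSV
#'
#' @param path TSV with columns `disease_id`, `term_id`, `weight`.
#' @param modality modality tag attached to each profile.
#' @return named list of annotation profiles.
#' @export
readAnnotations <- function(path, modality = "unspecified") {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("disease_id", "term_id", "weight") %in% names(x)))
  split(x, x$disease_id) |>
    lapply(function(d) .newProfile(d$disease_id[[1L]], modality,
                                   d$term_id, d$weight))
}

#' Write/read a similarity matrix as TSV (ids as header row and column)
#'
#' @param sim a [SimilarityMatrix-class] or matrix.
#' @param path output path.
#' @param what `"scores"` or `"pvalues"`.
#' @return `path`, invisibly.
#' @export
writeSimilarityTSV <- function(sim, path, what = c("scores", "pvalues")) {
  what <- match.arg(what)
  m <- if (is(sim, "SimilarityMatrix")) {
    if (what == "scores") simScores(sim) else simPvalues(sim)
  } else sim
  if (is.null(m)) stop("no ", what, " to write")
  write.table(data.frame(disease_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSimilarityTSV
#' @export
readSimilarityTSV <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$disease_id
  storage.mode(m) <- "double"
  m
}
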