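# Per-modality annotation profiles: a disease's weighted ontology-term set.
# Represented as a data.frame with columns `term`, `weight` and attributes
# `diseaseId` and `modality` (S3 class "annotationProfile").

.newProfile <- function(diseaseId, modality, term, weight) {
  p <- data.frame(term = term, weight = weight, stringsAsFactors = FALSE)
  attr(p, "diseaseId") <- diseaseId
  attr(p, "modality") <- modality
  class(p) <- c("annotationProfile", "data.frame")
  p
}

#' @export
print.annotationProfile <- function(x, ...) {
  cat(sprintf("annotationProfile: %s (%s), %d term(s)\n",
              attr(x, "diseaseId"), attr(x, "modality"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Build a disease's annotation profile in one modality
#'
#' Maps raw items (genes, phenotype ids, cell types, ...) to ontology terms,
#' merges duplicate terms by maximum weight, and optionally retains only the
#' `topK` terms by weight (descending; ties broken by lexicographic term id
#' for determinism).  An item mapping to several terms annotates each.
#'
#' @param diseaseId disease identifier.
#' @param modality one of `"genetic"`, `"transcriptomic"`, `"phenotypic"`,
#'   `"cellular"`, `"drug"`.
#' @param items data.frame with columns `item` and optionally `weight`
#'   (default 1), or a character vector of items (weight 1).
#' @param mapping data.frame with columns `item`, `term`; `NULL` means items
#'   already are term ids.
#' @param topK integer or `NULL`; retain the `topK` largest-weight terms.
#' @return an `annotationProfile` (zero rows if nothing mapped, with a
#'   message; such diseases are excluded downstream).
#' @export
buildProfile <- function(diseaseId, modality, items, mapping = NULL,
                         topK = NULL) {
  modality <- match.arg(modality, c("genetic", "transcriptomic", "phenotypic",
                                    "cellular", "drug"))
  if (is.character(items))
    items <- data.frame(item = items, weight = 1, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(items), "item" %in% names(items))
  if (is.null(items$weight)) items$weight <- 1
  if (any(items$weight < 0)) stop("item weights must be >= 0")

  if (is.null(mapping)) {
    mapped <- data.frame(term = items$item, weight = items$weight,
                         stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("item", "term") %in% names(mapping)))
    m <- merge(items, mapping, by = "item")
    mapped <- data.frame(term = m$term, weight = m$weight,
                         stringsAsFactors = FALSE)
  }
  if (!nrow(mapped)) {
    message("disease ", diseaseId, ": no mappable item; empty profile")
    return(.newProfile(diseaseId, modality, character(0), numeric(0)))
  }
  w <- tapply(mapped$weight, mapped$term, max)
  terms <- names(w)
  w <- as.numeric(w)
  if (!is.null(topK) && length(terms) > topK) {
    ord <- order(-w, terms)[seq_len(topK)]
    terms <- terms[ord]
    w <- w[ord]
  }
  ord <- order(terms)
  .newProfile(diseaseId, modality, terms[ord], w[ord])
}

#' Cell-type proportion profile for single-cell-level similarity
#'
#' Normalizes per-disease cell-type counts to proportions (summing to 1) and
#' maps cell types to Cell Ontology ids; the proportions serve as term
#' weights in the best-match-average similarity.
#'
#' @param diseaseId disease identifier.
#' @param counts named non-negative numeric vector of cell-type counts.
#' @param clIds named character map cell type -> Cell Ontology term id.
#' @return an `annotationProfile` with modality `"cellular"`.
#' @export
cellProportionProfile <- function(diseaseId, counts, clIds) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0)) stop("cell counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) stop("all-zero cell counts for disease ", diseaseId)
  missing <- setdiff(names(counts), names(clIds))
  if (length(missing))
    stop("no Cell Ontology id for cell type(s): ",
         paste(missing, collapse = ", "))
  props <- counts / total
  terms <- clIds[names(counts)]
  w <- tapply(props, terms, sum)  # cell types sharing an id pool their mass
  ord <- order(names(w))
  .newProfile(diseaseId, "cellular", names(w)[ord], as.numeric(w)[ord])
}

#' Per-cell-type consistency ratio between two proportion profiles
#'
#' For each shared cell type, `max(p1, p2) / min(p1, p2)` (>= 1; 1 means
#' identical proportions).  Ratios are returned sorted ascending so the most
#' consistent cell types rank first.
#'
#' @param p1,p2 named numeric proportion vectors (cell type -> proportion).
#' @param cellType optional single cell type; return its ratio only.
#' @return named numeric vector of ratios (ascending), or a single ratio.
#' @export
cellConsistencyRatio <- function(p1, p2, cellType = NULL) {
  shared <- intersect(names(p1), names(p2))
  if (!is.null(cellType)) {
    if (!cellType %in% shared)
      stop("cell type '", cellType, "' absent from one of the profiles")
    shared <- cellType
  }
  a <- p1[shared]; b <- p2[shared]
  if (any(pmin(a, b) <= 0))
    stop("consistency ratio undefined for zero proportions: ",
         paste(shared[pmin(a, b) <= 0], collapse = ", "))
  r <- pmax(a, b) / pmin(a, b)
  if (!is.null(cellType)) return(unname(r))
  sort(r)
}

# Coerce a named list of profiles/data.frames into the internal form used by
# the similarity kernels: named list of data.frame(term, weight).
.asProfileList <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  lapply(profiles, function(p) {
    stopifnot(is.data.frame(p), all(c("term", "weight") %in% names(p)))
    p[, c("term", "weight"), drop = FALSE]
  })
}
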