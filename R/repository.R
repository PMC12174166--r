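# Multi-source AD/AID classification repository: binary AIID classification
# score (ACS), confidence-weighted normalized ACS on [-1, +1], and the
# AD / AID / CA (contested) / AA (phenotype-associated) category assignment.

#' Default classification-source confidence weights
#'
#' Mondo 1.0, DO 0.8, MeSH 0.7, ICD 0.7, expert panel lists 1.0, and the
#' specialized AIID knowledge bases AA/ARI/GAI 1.0.
#'
#' @return named numeric vector of source weights.
#' @export
defaultSourceWeights <- function() {
  c(Mondo = 1.0, DO = 0.8, MeSH = 0.7, ICD = 0.7,
    expert = 1.0, AA = 1.0, ARI = 1.0, GAI = 1.0)
}

.checkLabels <- function(labels) {
  stopifnot(is.data.frame(labels), all(c("source", "label") %in% names(labels)))
  if (!all(labels$label %in% c("AD", "AID")))
    stop("labels must be 'AD' or 'AID'")
  if (anyDuplicated(labels[, c("source", "label")]))
    stop("duplicate (source, label) pair for one disease")
  labels
}

#' Binary AIID classification score
#'
#' Each source classifying the disease as autoimmune (AD) contributes +1,
#' as autoinflammatory (AID) -1.
#'
#' @param labels data.frame with columns `source`, `label` (one disease's
#'   labels; at most one label per source and polarity).
#' @return integer ACS.
#' @export
computeACS <- function(labels) {
  labels <- .checkLabels(labels)
  as.integer(sum(labels$label == "AD") - sum(labels$label == "AID"))
}

#' Confidence-weighted normalized classification score
#'
#' Weighted mean of per-source classification states `s_i` (+1 for AD, -1 for
#' AID, 0 for a covering source that leaves the disease unclassified):
#' `sum(w_i * s_i) / sum(w_i)`, a value on \[-1, +1\].  A source labeling a
#' disease both AD and AID contributes `s_i = 0`.
#'
#' @param labels data.frame with columns `source`, `label` for one disease.
#' @param weights named numeric source weights (must cover every labeled
#'   source); defaults to [defaultSourceWeights()].
#' @param covered optional character vector of sources that cover the disease
#'   without labeling it; they enter the denominator with `s_i = 0`.  Sources
#'   not listed and not labeling are excluded entirely.
#' @return numeric in \[-1, 1\].
#' @export
computeACSNorm <- function(labels, weights = defaultSourceWeights(),
                           covered = character(0)) {
  labels <- .checkLabels(labels)
  srcs <- unique(c(labels$source, covered))
  missW <- setdiff(srcs, names(weights))
  if (length(missW))
    stop("no confidence weight configured for source(s): ",
         paste(missW, collapse = ", "))
  s <- vapply(srcs, function(src) {
    lab <- labels$label[labels$source == src]
    sum(lab == "AD") - sum(lab == "AID")
  }, numeric(1))
  w <- weights[srcs]
  sum(w * sign(s)) / sum(w)
}

#' Assign the repository category of a disease
#'
#' Contested (CA) if both polarities appear anywhere in its labels; else AD
#' if ACS >= 1, AID if ACS <= -1; else AA when the disease carries the
#' HPO "autoimmunity" phenotype flag without any AIID label; else
#' unclassified.
#'
#' @param labels data.frame with columns `source`, `label` for one disease
#'   (possibly zero rows).
#' @param hasAutoimmunityPhenotype logical; HP:0002960 flag.
#' @return one of `"AD"`, `"AID"`, `"CA"`, `"AA"`, `"unclassified"`.
#' @export
assignCategory <- function(labels, hasAutoimmunityPhenotype = FALSE) {
  labels <- .checkLabels(labels)
  both <- any(labels$label == "AD") && any(labels$label == "AID")
  if (both) return("CA")
  acs <- computeACS(labels)
  if (acs >= 1) return("AD")
  if (acs <= -1) return("AID")
  if (hasAutoimmunityPhenotype && nrow(labels) == 0) return("AA")
  "unclassified"
}

#' Integrate multi-source classification tables into a disease repository
#'
#' Builds one record per unique disease id with its binary ACS, normalized
#' ACS and category, plus summary counts per category and the fraction of
#' AD/AID diseases recognized by exactly one source (|ACS| = 1).
#' Exact duplicate rows are logged and deduplicated.
#'
#' @param labels data.frame with columns `disease_id`, `source`, `label`.
#' @param phenotypeFlags character vector of disease ids carrying the HPO
#'   autoimmunity phenotype; unlabeled flagged diseases become AA records.
#' @param weights named source confidence weights for the normalized score.
#' @return list with `records` (data.frame: `disease_id`, `acs`, `acs_norm`,
#'   `category`, `n_sources`) and `summary` (category counts and per-category
#'   |ACS| = 1 fractions, computed over AD/AID records only, mirroring the
#'   exclusion of contested diseases from those tallies).
#' @export
integrateSources <- function(labels, phenotypeFlags = character(0),
                             weights = defaultSourceWeights()) {
  stopifnot(is.data.frame(labels),
            all(c("disease_id", "source", "label") %in% names(labels)))
  dup <- duplicated(labels[, c("disease_id", "source", "label")])
  if (any(dup)) {
    message("deduplicated ", sum(dup), " duplicate label row(s)")
    labels <- labels[!dup, , drop = FALSE]
  }
  ids <- unique(c(labels$disease_id, phenotypeFlags))
  flagged <- ids %in% phenotypeFlags
  recs <- lapply(seq_along(ids), function(i) {
    lab <- labels[labels$disease_id == ids[[i]], c("source", "label"),
                  drop = FALSE]
    data.frame(
      disease_id = ids[[i]],
      acs = computeACS(lab),
      acs_norm = if (nrow(lab)) computeACSNorm(lab, weights) else 0,
      category = assignCategory(lab, flagged[[i]]),
      n_sources = length(unique(lab$source)),
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)

  counts <- table(factor(records$category,
                         levels = c("AD", "AID", "CA", "AA", "unclassified")))
  singleFrac <- vapply(c("AD", "AID"), function(cat) {
    sub <- records[records$category == cat, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    mean(abs(sub$acs) == 1)
  }, numeric(1))
  list(records = records,
       summary = list(categoryCounts = as.list(counts),
                      singleSourceFraction = as.list(singleFrac)))
}
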