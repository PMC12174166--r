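# OBO 1.2/1.4 flat-file reading and writing for ontology DAGs.  Only the
# fields the similarity machinery needs are parsed: [Term] stanzas with id,
# name, is_a, relationship, is_obsolete and replaced_by lines.

#' Load an OBO ontology into an OntologyDAG
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file.  Obsolete terms are
#' dropped (with a message reporting the count); their `replaced_by` targets
#' are retained on the returned object so annotations can be remapped with
#' [remapTerms()].  Cyclic input is rejected with a validity error naming one
#' cycle member.
#'
#' @param path path to an OBO file.
#' @param edgeWeights named numeric map from relation kind to semantic
#'   contribution factor in (0, 1).  Defaults to the standard Wang-method
#'   constants `is_a = 0.8`, `part_of = 0.6`.
#' @return an [OntologyDAG-class].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: T:1", "name: root", "",
#'   "[Term]", "id: T:2", "name: child", "is_a: T:1 ! root"), obo)
#' dag <- loadOntology(obo)
#' ontologyRoots(dag)
#' @export
loadOntology <- function(path,
                         edgeWeights = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  inTerm <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush()
      inTerm <- identical(ln, "[Term]")
      if (inTerm) cur <- list(line = i, id = NULL, name = NA_character_,
                              parents = character(0), relations = character(0),
                              obsolete = FALSE, replacedBy = NA_character_)
      next
    }
    if (!inTerm) next
    colon <- regexpr(": ", ln, fixed = TRUE)
    if (colon < 0) next
    key <- substr(ln, 1L, colon - 1L)
    val <- sub(" !.*$", "", substr(ln, colon + 2L, nchar(ln)))
    val <- trimws(val)
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "[[:space:]]+")[[1L]]
      if (length(parts) < 2L)
        stop("OBO parse error at line ", i, ": malformed relationship '",
             lines[[i]], "'")
      cur$parents <- c(cur$parents, parts[[2L]])
      cur$relations <- c(cur$relations, parts[[1L]])
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    } else if (key == "replaced_by") {
      cur$replacedBy <- val
    }
  }
  flush()

  if (!length(stanzas)) stop("OBO parse error: no [Term] stanzas in ", path)
  noId <- vapply(stanzas, function(s) is.null(s$id), logical(1))
  if (any(noId))
    stop("OBO parse error at line ", stanzas[[which(noId)[1L]]]$line,
         ": [Term] stanza without an id")

  obsolete <- vapply(stanzas, `[[`, logical(1), "obsolete")
  if (any(obsolete))
    message("dropped ", sum(obsolete), " obsolete term(s)")
  replacedBy <- vapply(stanzas[obsolete], `[[`, character(1), "replacedBy")
  names(replacedBy) <- vapply(stanzas[obsolete], `[[`, character(1), "id")
  replacedBy <- replacedBy[!is.na(replacedBy)]
  stanzas <- stanzas[!obsolete]

  ids <- vapply(stanzas, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("OBO parse error: duplicate term id '", ids[duplicated(ids)][1L], "'")
  parents <- lapply(stanzas, `[[`, "parents")
  relations <- lapply(stanzas, `[[`, "relations")
  # drop edges to obsolete parents
  keep <- lapply(parents, function(p) !(p %in% names(replacedBy)) | p %in% ids)
  parents <- Map(function(p, k) p[k | p %in% ids], parents, keep)
  relations <- Map(`[`, relations, lapply(parents, function(p) seq_along(p)))
  names(parents) <- names(relations) <- ids

  missing <- setdiff(unique(unlist(parents)), ids)
  if (length(missing))
    stop("OBO parse error: parent term(s) not defined: ",
         paste(head(missing, 3), collapse = ", "))

  usedRel <- unique(unlist(relations))
  unknownRel <- setdiff(usedRel, names(edgeWeights))
  if (length(unknownRel))
    stop("no edge contribution factor configured for relation(s): ",
         paste(unknownRel, collapse = ", "))

  new("OntologyDAG",
      terms = ids,
      termNames = vapply(stanzas, `[[`, character(1), "name"),
      parents = parents,
      relations = relations,
      edgeWeights = edgeWeights,
      rootIds = ids[vapply(parents, length, integer(1)) == 0L],
      replacedBy = replacedBy)
}

#' Write an OntologyDAG as an OBO flat file
#'
#' Emits `[Term]` stanzas sorted by term id; `is_a` edges as `is_a:` lines,
#' other relations as `relationship:` lines.  Output round-trips through
#' [loadOntology()] to an identical DAG.
#'
#' @param dag an [OntologyDAG-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(dag, path) {
  stopifnot(is(dag, "OntologyDAG"))
  out <- c("format-version: 1.2", "")
  for (id in sort(dag@terms)) {
    i <- match(id, dag@terms)
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", dag@termNames[[i]]))
    ps <- dag@parents[[id]]
    rs <- dag@relations[[id]]
    if (length(ps)) {
      ord <- order(ps)
      for (k in ord) {
        out <- c(out, if (rs[[k]] == "is_a") paste0("is_a: ", ps[[k]])
                      else paste0("relationship: ", rs[[k]], " ", ps[[k]]))
      }
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Remap annotation term ids through an ontology's replaced_by table
#'
#' Terms annotated to obsolete ids are remapped when a `replaced_by` target
#' exists, otherwise discarded (with a message).
#'
#' @param terms character vector of term ids.
#' @param dag an [OntologyDAG-class].
#' @return character vector of valid term ids (possibly shorter).
#' @export
remapTerms <- function(terms, dag) {
  hit <- terms %in% names(dag@replacedBy)
  terms[hit] <- dag@replacedBy[terms[hit]]
  bad <- !(terms %in% dag@terms)
  if (any(bad))
    message("discarded ", sum(bad), " annotation(s) to unknown/obsolete terms")
  terms[!bad]
}
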