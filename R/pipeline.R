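# End-to-end orchestration on a synthetic scenario: repository -> profiles
# -> OADS -> permutation -> networks -> communities -> integration, with a
# reproducible run manifest (per-stage outputs, content hashes, seeds,
# counts).  Rerunning with the same configuration reproduces identical
# hashes.

#' Default pipeline run configuration
#'
#' @param outputDir output directory (created if absent).
#' @param scenario a [syntheticScenario()] describing the synthetic inputs.
#' @param percentile network percentile cut (study default 90).
#' @param alpha significance cut (study default 0.05).
#' @param nPermutations permutation count (study default 500).
#' @param leidenResolution Leiden resolution (study default 1.0).
#' @param snfK,snfT SNF neighborhood size and iteration count (study
#'   defaults 10 and 20).
#' @param seed integer seed for the stochastic stages.
#' @return a named list, suitable for [runPipeline()].
#' @export
pipelineConfig <- function(outputDir,
                           scenario = syntheticScenario(),
                           percentile = 90, alpha = 0.05,
                           nPermutations = 500L,
                           leidenResolution = 1.0,
                           snfK = 10L, snfT = 20L, seed = 1L) {
  list(outputDir = outputDir, scenario = scenario, percentile = percentile,
       alpha = alpha, nPermutations = as.integer(nPermutations),
       leidenResolution = leidenResolution, snfK = as.integer(snfK),
       snfT = as.integer(snfT), seed = as.integer(seed))
}

.validateConfig <- function(config) {
  req <- c("outputDir", "scenario", "percentile", "alpha", "nPermutations",
           "leidenResolution", "snfK", "snfT", "seed")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  if (config$percentile <= 0 || config$percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (config$nPermutations < 1L) stop("nPermutations must be >= 1")
  if (!inherits(config$scenario, "syntheticScenario"))
    stop("scenario must be built with syntheticScenario()")
  invisible(config)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes, in dependency order: synthetic-data generation (ontology OBO,
#' classification labels, per-modality annotations), repository integration,
#' per-modality OADS with permutation significance, network construction and
#' topology, Ward + Leiden community detection with robust-community
#' consensus and feature enrichment, similarity network fusion, and an MST
#' trajectory on the first term modality.  Every output file is listed in
#' the returned manifest with an md5 content hash; a rerun with the same
#' configuration reproduces identical hashes.
#'
#' @param config a configuration list from [pipelineConfig()].
#' @return the manifest (list of stages, files, hashes and counts),
#'   invisibly; also written as `manifest.json` in the output directory.
#' @export
runPipeline <- function(config) {
  .validateConfig(config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outputDir, ...)
  manifest <- list(config = list(
    percentile = config$percentile, alpha = config$alpha,
    nPermutations = config$nPermutations,
    leidenResolution = config$leidenResolution,
    snfK = config$snfK, snfT = config$snfT, seed = config$seed,
    scenario = unclass(config$scenario)))
  files <- character(0)
  addStage <- function(name, stageFiles, counts = list()) {
    files <<- c(files, stageFiles)
    manifest$stages[[name]] <<- list(
      files = basename(stageFiles),
      md5 = unname(tools::md5sum(stageFiles)),
      counts = counts)
  }

  # 1. synthetic inputs ------------------------------------------------
  gen <- genAnnotations(config$scenario)
  lab <- genClassificationLabels(config$scenario)
  writeOBO(gen$dag, out("ontology.obo"))
  write.table(lab$labels, out("labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  annotFiles <- character(0)
  for (m in names(gen$profiles)) {
    f <- out(paste0("annotations_", m, ".tsv"))
    writeAnnotations(gen$profiles[[m]], f)
    annotFiles <- c(annotFiles, f)
  }
  planted <- out("planted_communities.tsv")
  write.table(data.frame(disease_id = names(gen$labels),
                         community = gen$labels),
              planted, sep = "\t", quote = FALSE, row.names = FALSE)
  addStage("synthetic_data",
           c(out("ontology.obo"), out("labels.tsv"), annotFiles, planted),
           list(nTerms = length(ontologyTerms(gen$dag)),
                nDiseases = config$scenario$nDiseases))

  # 2. repository -------------------------------------------------------
  labels <- read.delim(out("labels.tsv"), stringsAsFactors = FALSE)
  repo <- integrateSources(labels)
  write.table(repo$records, out("repository.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(repo$summary, out("repository_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  addStage("repository", c(out("repository.tsv"),
                           out("repository_summary.json")),
           list(categories = repo$summary$categoryCounts))

  # 3. OADS + permutation significance ----------------------------------
  dag <- loadOntology(out("ontology.obo"))
  sims <- list()
  simFiles <- character(0)
  counts <- list()
  for (m in names(gen$profiles)) {
    profiles <- readAnnotations(out(paste0("annotations_", m, ".tsv")),
                                modality = m)
    weighted <- m %in% c("transcriptomic", "cellular")
    sims[[m]] <- oadsSignificance(profiles, dag,
                                  nPermutations = config$nPermutations,
                                  seed = config$seed, weighted = weighted,
                                  modality = m)
    fs <- out(paste0("oads_", m, ".tsv"))
    fp <- out(paste0("oads_", m, "_pvalues.tsv"))
    writeSimilarityTSV(sims[[m]], fs, "scores")
    writeSimilarityTSV(sims[[m]], fp, "pvalues")
    simFiles <- c(simFiles, fs, fp)
    counts[[m]] <- length(diseaseIds(sims[[m]]))
  }
  addStage("oads", simFiles, counts)

  # 4. networks + topology ----------------------------------------------
  nets <- list()
  netFiles <- character(0)
  netCounts <- list()
  for (m in names(sims)) {
    nets[[m]] <- buildNetwork(sims[[m]], config$percentile, config$alpha)
    f <- out(paste0("network_", m, ".tsv"))
    exportNetwork(nets[[m]], f)
    netFiles <- c(netFiles, f)
    g <- networkGraph(nets[[m]])
    netCounts[[m]] <- list(nodes = igraph::vcount(g),
                           edges = igraph::ecount(g))
    if (igraph::ecount(g) > 0L) {
      topo <- topologySummary(nets[[m]])
      topo$centrality <- NULL
      ft <- out(paste0("topology_", m, ".json"))
      jsonlite::write_json(topo, ft, auto_unbox = TRUE, digits = NA)
      netFiles <- c(netFiles, ft)
    }
  }
  addStage("network", netFiles, netCounts)

  # 5. communities -------------------------------------------------------
  partitions <- list()
  partFiles <- character(0)
  for (m in names(nets)) {
    if (igraph::ecount(networkGraph(nets[[m]])) == 0L) next
    lp <- leidenClusters(nets[[m]], resolution = config$leidenResolution,
                         seed = config$seed)
    nc <- max(2L, length(unique(partitionMembership(lp))))
    wp <- wardClusters(sims[[m]], nClusters = nc)
    partitions[[paste0(m, "_leiden")]] <- lp
    partitions[[paste0(m, "_ward")]] <- wp
    for (tag in paste0(m, c("_leiden", "_ward"))) {
      f <- out(paste0("partition_", tag, ".tsv"))
      mem <- partitionMembership(partitions[[tag]])
      write.table(data.frame(disease_id = names(mem), label = mem),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      partFiles <- c(partFiles, f)
    }
  }
  consensusFiles <- character(0)
  if (length(partitions) >= 2L) {
    cats <- setNames(repo$records$category, repo$records$disease_id)
    robust <- robustCommunities(partitions, minSize = 4L, categories = cats)
    memRows <- do.call(rbind, lapply(robust, function(com)
      data.frame(community = com$id, disease_id = com$members,
                 stringsAsFactors = FALSE)))
    f <- out("robust_communities.tsv")
    write.table(memRows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    consensusFiles <- f
    features <- lapply(gen$profiles[[1L]], function(p) p$term)
    inUniverse <- unique(memRows$disease_id)
    enr <- tryCatch(featureEnrichment(robust, features),
                    error = function(e) NULL)
    if (!is.null(enr)) {
      fe <- out("enrichment.tsv")
      write.table(enr, fe, sep = "\t", quote = FALSE, row.names = FALSE)
      consensusFiles <- c(consensusFiles, fe)
    }
  }
  addStage("communities", c(partFiles, consensusFiles),
           list(nPartitions = length(partitions)))

  # 6. integration --------------------------------------------------------
  intFiles <- character(0)
  shared <- Reduce(intersect, lapply(sims, diseaseIds))
  if (length(sims) >= 2L && length(shared) > config$snfK) {
    mats <- lapply(sims, function(s) simScores(s)[shared, shared])
    fused <- snfFuse(mats, K = config$snfK, t = config$snfT)
    f <- out("fused.tsv")
    writeSimilarityTSV(fused, f)
    intFiles <- c(intFiles, f)
  }
  mst <- buildMST(sims[[1L]], config$percentile, config$alpha)
  fm <- out("mst.tsv")
  write.table(mst, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  intFiles <- c(intFiles, fm)
  addStage("integration", intFiles,
           list(sharedDiseases = length(shared),
                mstComponents = attr(mst, "nComponents")))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
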