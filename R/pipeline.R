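# End-to-end orchestration: typed readers for the standard input formats,
# a flat config, and the staged workflow QC -> DE -> panel -> weighting/
# seeds -> Steiner tree -> DAG/SEM -> communities -> survival.

#' Read a counts matrix (TSV or MatrixMarket)
#'
#' TSV: first column gene ids, remaining columns samples. MTX: a
#' MatrixMarket file with `<stem>.rownames` / `<stem>.colnames` sidecar
#' files, one id per line.
#'
#' @param path file path (`.tsv`/`.txt` or `.mtx`)
#' @return integer gene x sample matrix
#' @export
readCounts <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rn <- readLines(paste0(stem, ".rownames"))
    cn <- readLines(paste0(stem, ".colnames"))
    .stopIf(length(rn) != nrow(m) || length(cn) != ncol(m),
            "sidecar name files do not match the matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  .stopIf(anyDuplicated(rownames(m)) > 0, "duplicated gene ids in %s", path)
  .stopIf(anyDuplicated(colnames(m)) > 0, "duplicated sample ids in %s", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  .stopIf(nrow(bad) > 0, "non-count entry at row %d of %s", bad[1, 1], path)
  storage.mode(m) <- "integer"
  m
}

#' Read sample metadata (CSV)
#'
#' Requires `sample_id` and `group` columns; `group` values are mapped to
#' `case`/`control` (values `case`, `tumor`, `CRC`, `1` count as case).
#'
#' @param path CSV path
#' @return data.frame keyed by `sample_id`
#' @export
readSampleMetadata <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stopIf(!all(c("sample_id", "group") %in% names(meta)),
          "metadata needs sample_id and group columns")
  .stopIf(anyDuplicated(meta$sample_id) > 0, "duplicated sample ids in %s", path)
  grp <- tolower(as.character(meta$group))
  meta$group <- factor(ifelse(grp %in% c("case", "tumor", "crc", "1"),
                              "case", "control"),
                       levels = c("case", "control"))
  rownames(meta) <- meta$sample_id
  meta
}

#' Read a gene panel (one symbol per line)
#' @param path text file path
#' @return character vector
#' @export
readPanel <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  p <- trimws(readLines(path))
  p[nzchar(p)]
}

#' Read gene-set membership in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT path
#' @return named list of character vectors
#' @export
readGmt <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .stopIf(length(f) < 3, "malformed GMT line %d in %s", i, path)
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Read directed pathway edges in SIF format
#'
#' Tab-separated `source relation target` with an optional fourth `pathway`
#' column; without it all edges belong to one pathway named after the file.
#'
#' @param path SIF path
#' @return named list of directed `igraph` pathway graphs
#' @export
readSif <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- identical(tolower(first[1:3]), c("source", "relation", "target"))
  df <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  .stopIf(ncol(df) < 3, "malformed SIF file %s", path)
  names(df)[1:3] <- c("source", "relation", "target")
  pw <- if (ncol(df) >= 4) df[[4]] else
    rep(sub("\\.sif$", "", basename(path)), nrow(df))
  lapply(split(df[, c("source", "target")], pw), function(e)
    igraph::graph_from_edgelist(as.matrix(e), directed = TRUE))
}

#' Read a survival table (CSV: sample_id, time, event)
#' @param path CSV path
#' @return validated data.frame
#' @export
readSurvival <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stopIf(!all(c("sample_id", "time", "event") %in% names(df)),
          "survival table needs sample_id, time, event")
  .checkRecords(df)
}

#' Pipeline configuration
#'
#' Collects the workflow thresholds (the defaults are the study's printed
#' settings: 25M-read QC, >10 counts in >= 10 samples, padj < 0.01 with
#' |log2FC| >= 1, alpha 0.05, beta grid 0.05..0.15 by 0.01, walk length 4)
#' together with input paths or a synthetic-study configuration.
#'
#' @param paths named list of input paths (`counts`, `metadata`, `panel`,
#'   `gmt`, `sif`, `survival`); ignored in synthetic mode
#' @param synthetic `NULL`, or a [simConfig()] to generate inputs in memory
#' @param qc_min_reads,de_padj,de_lfc,alpha,beta_grid,walk_t,pseudocount,pca_k
#'   stage thresholds
#' @param module_mode edge significance mode for the active module
#' @param steiner_closure re-add interactome edges among tree nodes
#' @param stages character vector of stages to run (any of `"survival"`,
#'   `"communities"` may be dropped)
#' @param seed master seed
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(paths = list(), synthetic = NULL,
                           qc_min_reads = 25e6, de_padj = 0.01, de_lfc = 1,
                           alpha = 0.05,
                           beta_grid = seq(0.05, 0.15, by = 0.01),
                           walk_t = 4L, pseudocount = 1, pca_k = 500,
                           module_mode = "difference",
                           steiner_closure = FALSE,
                           stages = c("communities", "survival"),
                           seed = 1L) {
  cfg <- as.list(environment())
  .stopIf(de_padj <= 0 || de_padj > 1, "de_padj must lie in (0, 1]")
  .stopIf(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  .stopIf(qc_min_reads < 0, "qc_min_reads must be >= 0")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full active-module pipeline
#'
#' Executes the stages in workflow order — sample QC, gene filtering,
#' normalization, PCA, differential expression, panel intersection, seed
#' selection, interactome weighting, Steiner tree, optimal-DAG SEM fitting,
#' perturbation inference, community detection, and survival validation —
#' and returns every artifact in a result bundle with a reproducibility
#' manifest. Identical config and seed give an identical bundle.
#'
#' @param config a [pipelineConfig()]
#' @param outdir optional directory; when given, every artifact is also
#'   written as TSV/JSON
#' @return list of class `ResultBundle`
#' @export
runPipeline <- function(config = pipelineConfig(synthetic = simConfig()),
                        outdir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    study <- simulateStudy(config$synthetic)
    se <- study$se
    panel <- study$panel
    pathways <- study$pathways
    survTab <- study$survival
    truth <- study$truth
  } else {
    counts <- readCounts(config$paths$counts)
    meta <- readSampleMetadata(config$paths$metadata)
    .stopIf(!all(colnames(counts) %in% meta$sample_id),
            "metadata missing for some samples")
    se <- countsExperiment(counts, meta[colnames(counts), , drop = FALSE])
    panel <- readPanel(config$paths$panel)
    pathways <- readSif(config$paths$sif)
    survTab <- if (!is.null(config$paths$survival))
      readSurvival(config$paths$survival) else NULL
  }

  message("stage qc: ", ncol(se), " samples in")
  se <- qcFilterSamples(se, config$qc_min_reads)
  se <- filterGenes(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  groups <- SummarizedExperiment::colData(se)$group

  sf <- sizeFactorsMedianOfRatios(counts)
  normalized <- normalizeLog(counts, sf, config$pseudocount)
  pca <- pcaTopVariable(normalized, k = config$pca_k,
                        metadata = as.data.frame(
                          SummarizedExperiment::colData(se)[,
                            intersect(c("group", "sex", "grade"),
                                      colnames(SummarizedExperiment::colData(se))),
                            drop = FALSE]))
  de <- differentialExpression(normalized, groups,
                               padj_cut = config$de_padj,
                               lfc_cut = config$de_lfc)
  message(sprintf("stage de: %d DEGs (%d up, %d down) of %d genes",
                  sum(de$status != "ns"), sum(de$status == "up"),
                  sum(de$status == "down"), nrow(de)))
  icdeg <- intersectPanel(de, panel)
  message(sprintf("stage panel: %d panel DEGs", nrow(icdeg)))

  interactome <- buildInteractome(pathways)
  measured <- intersect(igraph::V(interactome)$name, rownames(normalized))
  npn <- nonparanormalTransform(normalized[measured, , drop = FALSE])
  seeds <- selectSeeds(pathways, npn, groups, alpha = config$alpha)
  seedGenes <- seeds$gene[seeds$seed]
  message(sprintf("stage seeds: %d seed genes of %d screened",
                  length(seedGenes), nrow(seeds)))
  el <- igraph::as_edgelist(interactome, names = TRUE)
  el <- el[el[, 1L] %in% measured & el[, 2L] %in% measured, , drop = FALSE]
  stats_ <- edgeCorrelationTest(npn, groups, el)
  weighted <- weightEdges(stats_, graph = interactome)
  st <- kouSteiner(weighted, seedGenes, closure = config$steiner_closure)
  message(sprintf("stage steiner: %d nodes, %d edges (%d terminals)",
                  igraph::vcount(moduleGraph(st)),
                  igraph::ecount(moduleGraph(st)), length(terminals(st))))

  oo <- orientAndOrder(st, reference = interactome)
  modGenes <- oo$order
  z <- npn[modGenes, , drop = FALSE]
  z <- z / apply(z, 1L, stats::sd)          # standardized scale for the grid
  candidates <- dagNodewiseLasso(z, oo$order, config$beta_grid)
  dag <- selectOptimalDag(candidates, z)
  message(sprintf("stage dag: tau = %.2f, %d edges", dag@tau, nrow(dag@edges)))
  pm <- fitPerturbationModel(dag, z, groups)
  fitIdx <- list(
    overall = srmr(dag, z)$srmr,
    case = srmr(pm@caseModel, z[, groups == "case", drop = FALSE])$srmr,
    control = srmr(pm@controlModel, z[, groups == "control", drop = FALSE])$srmr)
  module <- extractActiveModule(pm, alpha = config$alpha,
                                mode = config$module_mode)
  message(sprintf("stage module: %d significant nodes, %d significant edges; SRMR overall %.3f",
                  nrow(module@nodes), nrow(module@edges), fitIdx$overall))

  partitionDag <- partitionSt <- overlap <- enrichment <- NULL
  if ("communities" %in% config$stages) {
    partitionDag <- walktrapCommunities(dag2igraph(dag), t = config$walk_t)
    partitionSt <- walktrapCommunities(moduleGraph(st), t = config$walk_t)
    # reduced graph: significant module genes on the panel plus their
    # module neighbors (the focused sub-module of interest)
    panelSig <- intersect(module@nodes$gene, panel)
    nb <- unique(unlist(lapply(panelSig, function(g)
      if (g %in% igraph::V(module@graph)$name)
        igraph::V(module@graph)$name[igraph::neighbors(module@graph, g, mode = "all")]
      else character(0))))
    reduced <- union(panelSig, intersect(nb, module@nodes$gene))
    overlap <- overlapSummary(partitionDag, reduced)
    sets <- if (!is.null(config$paths$gmt)) readGmt(config$paths$gmt)
            else lapply(pathways, function(p) igraph::V(p)$name)
    universe <- names(communityMembership(partitionDag))
    comm <- split(names(communityMembership(partitionDag)),
                  communityMembership(partitionDag))
    enrichment <- do.call(rbind, lapply(names(comm), function(cid) {
      res <- oraHypergeometric(comm[[cid]],
                               lapply(sets, intersect, universe), universe)
      res$community <- cid
      res
    }))
    message(sprintf("stage communities: %d communities, Q = %.3f",
                    length(unique(communityMembership(partitionDag))),
                    modularityScore(partitionDag)))
  }

  survSummary <- NULL
  if ("survival" %in% config$stages && !is.null(survTab)) {
    genes <- intersect(module@nodes$gene, rownames(normalized))
    if (!is.null(truth)) genes <- union(genes, names(truth$surv_beta))
    genes <- intersect(genes, rownames(normalized))
    keep <- survTab$sample_id %in% colnames(normalized)
    survSummary <- survivalValidation(survTab[keep, , drop = FALSE],
                                      normalized, genes = genes)
    message(sprintf("stage survival: %d genes validated", nrow(survSummary)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("SteinerSEM")),
    seed = config$seed,
    config_hash = .configHash(config[setdiff(names(config), "paths")]),
    n_samples = ncol(se), n_genes = nrow(se))
  bundle <- structure(list(
    de_table = de, ic_degs = icdeg, pca = pca, size_factors = sf,
    weighted_edges = stats_, seeds = seeds, steiner = st,
    dag = dag, perturbation = pm, fit_indices = fitIdx,
    active_module = module, partition_dag = partitionDag,
    partition_st = partitionSt, overlap = overlap,
    enrichment = enrichment, survival_summary = survSummary,
    truth = truth, manifest = manifest), class = "ResultBundle")
  if (!is.null(outdir)) writeBundle(bundle, outdir)
  bundle
}

#' Convert a DagModel's edge set to an igraph
#' @param dag a [DagModel-class]
#' @return directed `igraph` over the model's nodes
#' @export
dag2igraph <- function(dag) {
  igraph::graph_from_data_frame(
    data.frame(from = dag@edges$parent, to = dag@edges$child),
    directed = TRUE, vertices = dag@order)
}

#' Write a result bundle to disk
#'
#' Tabular artifacts as TSV, fit indices and the manifest as JSON, graphs as
#' SIF plus node-attribute tables. Reruns with the same config and seed
#' produce byte-identical files.
#'
#' @param bundle a `ResultBundle` from [runPipeline()]
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(obj, name) {
    p <- file.path(dir, name)
    if (is.data.frame(obj)) .writeTsv(obj, p)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    paths <<- c(paths, p)
  }
  put(bundle$de_table, "de_table.tsv")
  put(bundle$ic_degs, "ic_degs.tsv")
  put(bundle$weighted_edges, "weighted_edges.tsv")
  put(bundle$seeds, "seeds.tsv")
  put(list(var_frac = as.list(bundle$pca$var_frac)), "pca_summary.json")
  st <- bundle$steiner
  el <- igraph::as_edgelist(moduleGraph(st), names = TRUE)
  put(data.frame(source = el[, 1], relation = "connects", target = el[, 2]),
      "steiner.sif")
  put(data.frame(gene = c(terminals(st), connectors(st)),
                 role = rep(c("terminal", "connector"),
                            c(length(terminals(st)), length(connectors(st))))),
      "steiner_nodes.tsv")
  put(bundle$dag@edges, "dag_edges.tsv")
  put(bundle$perturbation@nodeEffects, "node_effects.tsv")
  put(bundle$perturbation@edgeDiffs, "edge_differences.tsv")
  put(bundle$fit_indices, "fit_indices.json")
  put(bundle$active_module@nodes, "active_module_nodes.tsv")
  put(bundle$active_module@edges, "active_module_edges.tsv")
  if (!is.null(bundle$partition_dag))
    put(data.frame(gene = names(communityMembership(bundle$partition_dag)),
                   community = unname(communityMembership(bundle$partition_dag))),
        "communities.tsv")
  if (!is.null(bundle$overlap)) put(bundle$overlap, "overlap_summary.tsv")
  if (!is.null(bundle$enrichment)) put(bundle$enrichment, "enrichment.tsv")
  if (!is.null(bundle$survival_summary))
    put(bundle$survival_summary, "survival_summary.tsv")
  put(bundle$manifest, "manifest.json")
  invisible(paths)
}
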