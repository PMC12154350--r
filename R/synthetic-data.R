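#' Configuration for a synthetic two-group study
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the cohort design the pipeline targets: 185 case (tumor) and 157 control
#' (normal adjacent tissue) samples, a pathway network of 60 genes laid out
#' as a DAG with four planted communities, ten genes carrying a case-specific
#' mean shift (delta, in standardized log-expression units), five edges with a
#' case-specific coefficient change (delta-beta), negative-binomial counts,
#' and proportional-hazards survival linked to selected genes.
#'
#' @param seed master seed; every generator derives its own substream from it
#' @param n_case,n_control group sizes (each must be at least 4: the Fisher
#'   r-to-z test needs n - 3 > 0)
#' @param n_genes total genes in the count matrix (network + background)
#' @param dag_nodes number of genes in the causal DAG
#' @param dag_edge_prob between-community edge density of the DAG; within
#'   planted communities the density is `dag_p_in`
#' @param n_communities planted community count
#' @param dag_p_in within-community edge probability
#' @param n_perturbed_nodes,delta number of perturbed nodes and their
#'   standardized case mean shift
#' @param n_perturbed_edges,dbeta number of perturbed edges and the
#'   case-minus-control coefficient difference
#' @param beta_range absolute edge-coefficient range; signs are random
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha * mu^2); 0 gives Poisson counts
#' @param library_size_range declared sequencing depth range (reads), carried
#'   in sample metadata and used only by read-count QC
#' @param panel_fraction fraction of genes labeled as panel (e.g. ion-channel)
#'   genes
#' @param frac_de_background fraction of background (non-network) genes given
#'   a case shift of `bg_shift` natural-log units
#' @param bg_shift background differential-expression shift
#' @param baseline_logmean_range range of per-gene baseline log mean counts
#' @param surv_genes number of perturbed genes linked to survival
#' @param surv_beta_value log-hazard coefficient per unit expression for each
#'   survival-linked gene
#' @param baseline_hazard baseline hazard per time unit (0.1 puts the median
#'   null event time near 7)
#' @param censor_max upper bound of the uniform censoring time
#' @param n_pathways number of pathway files the DAG is split into
#' @return a list of class `SimConfig`
#' @export
simConfig <- function(seed = 1L, n_case = 185L, n_control = 157L,
                      n_genes = 2000L, dag_nodes = 60L, dag_edge_prob = 0.02,
                      n_communities = 4L, dag_p_in = 0.25,
                      n_perturbed_nodes = 10L, delta = 1,
                      n_perturbed_edges = 5L, dbeta = 0.8,
                      beta_range = c(0.4, 0.8), nb_dispersion = 0.05,
                      library_size_range = c(26e6, 60e6),
                      panel_fraction = 0.15, frac_de_background = 0.05,
                      bg_shift = 1.5,
                      baseline_logmean_range = log(c(20, 2000)),
                      surv_genes = 3L, surv_beta_value = log(2),
                      baseline_hazard = 0.1, censor_max = 15,
                      n_pathways = 6L) {
  cfg <- as.list(environment())
  .stopIf(n_case < 4L || n_control < 4L,
          "n_case and n_control must be >= 4 (Fisher test needs n - 3 > 0)")
  .stopIf(nb_dispersion < 0, "nb_dispersion must be >= 0")
  .stopIf(!is.finite(delta) || !is.finite(dbeta),
          "perturbation effects must be finite")
  .stopIf(dag_nodes > n_genes, "dag_nodes cannot exceed n_genes")
  .stopIf(panel_fraction < 0 || panel_fraction > 1,
          "panel_fraction must lie in [0, 1]")
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a random DAG
#'
#' Draws a random permutation of the nodes as ranks and adds each
#' lower-to-higher-rank pair independently with probability `edge_prob`;
#' edges always point from lower to higher rank, so the result is acyclic by
#' construction.
#'
#' @param n_nodes number of nodes (>= 1)
#' @param edge_prob edge probability in \[0, 1\]
#' @param seed integer seed
#' @param names optional node names (default `N001`, ...)
#' @return a directed acyclic `igraph`
#' @export
genDag <- function(n_nodes, edge_prob, seed = 1L, names = NULL) {
  .stopIf(n_nodes < 1, "n_nodes must be >= 1")
  .stopIf(edge_prob < 0 || edge_prob > 1, "edge_prob must lie in [0, 1]")
  if (is.null(names)) names <- sprintf("N%03d", seq_len(n_nodes))
  set.seed(.substream(seed, "genDag"))
  rank <- sample(n_nodes)
  ord <- names[order(rank)]
  from <- character(0); to <- character(0)
  if (n_nodes > 1L) {
    idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < edge_prob
    from <- ord[idx[keep, 1L]]
    to <- ord[idx[keep, 2L]]
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = names)
  if (length(from))
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  g
}

# block-structured DAG used by simulateStudy: nodes carry a planted community
# label; edge probability is p_in within a block, p_out between blocks
.genDagCommunities <- function(n_nodes, n_comm, p_in, p_out, seed,
                               names = NULL) {
  if (is.null(names)) names <- sprintf("NG%03d", seq_len(n_nodes))
  set.seed(.substream(seed, "genDagCommunities"))
  block <- sort(rep_len(seq_len(n_comm), n_nodes))
  ord <- sample(n_nodes)            # random topological rank
  nm_ord <- names[order(ord)]
  blk_ord <- block[order(ord)]
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1L)) {
    js <- (i + 1L):n_nodes
    p <- ifelse(blk_ord[js] == blk_ord[i], p_in, p_out)
    keep <- stats::runif(length(js)) < p
    from <- c(from, rep(nm_ord[i], sum(keep)))
    to <- c(to, nm_ord[js][keep])
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = names)
  g <- igraph::set_vertex_attr(g, "community", value = block[match(igraph::V(g)$name, names)])
  if (length(from)) g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  g
}

#' Generate latent two-group expression from a linear SEM on a DAG
#'
#' Each node is generated in topological order as a linear combination of its
#' parents plus standard Gaussian noise. Case samples use `beta + dbeta` on
#' perturbed edges and receive a `+delta` intercept on perturbed nodes;
#' control samples use the unperturbed coefficients and no shift. Values are
#' on a standardized log-expression scale.
#'
#' @param dag directed acyclic `igraph`
#' @param true_betas named numeric, `"parent|child"` -> coefficient, one per
#'   DAG edge
#' @param perturbed_nodes named numeric, gene -> delta mean shift (may be
#'   empty)
#' @param perturbed_edges named numeric, `"parent|child"` -> delta-beta (must
#'   be DAG edges)
#' @param n_case,n_control group sizes
#' @param seed integer seed
#' @return list with `expression` (gene x sample matrix, case columns first),
#'   `groups` (factor `case`/`control`), and `truth` (the planted ground
#'   truth)
#' @export
genTwoGroupExpression <- function(dag, true_betas, perturbed_nodes = numeric(0),
                                  perturbed_edges = numeric(0),
                                  n_case, n_control, seed = 1L) {
  el <- igraph::as_edgelist(dag, names = TRUE)
  keys <- if (nrow(el)) .edgeKey(el[, 1L], el[, 2L]) else character(0)
  .stopIf(!all(names(true_betas) %in% keys) || length(true_betas) != length(keys),
          "true_betas must name exactly the DAG edges as 'parent|child'")
  .stopIf(length(perturbed_edges) > 0 && !all(names(perturbed_edges) %in% keys),
          "perturbed edge not present in the DAG")
  .stopIf(any(!is.finite(c(perturbed_nodes, perturbed_edges))),
          "perturbation effects must be finite")
  nodes <- igraph::V(dag)$name
  ord <- nodes[as.integer(igraph::topo_sort(dag))]
  n <- n_case + n_control
  grp <- factor(rep(c("case", "control"), c(n_case, n_control)),
                levels = c("case", "control"))
  set.seed(.substream(seed, "genTwoGroupExpression"))
  x <- matrix(stats::rnorm(length(nodes) * n), nrow = length(nodes),
              dimnames = list(nodes, sprintf("S%04d", seq_len(n))))
  isCase <- grp == "case"
  parentsOf <- lapply(ord, function(v)
    nodes[igraph::neighbors(dag, v, mode = "in")])
  names(parentsOf) <- ord
  for (v in ord) {
    for (pa in parentsOf[[v]]) {
      b <- true_betas[[.edgeKey(pa, v)]]
      db <- perturbed_edges[.edgeKey(pa, v)]
      db <- if (is.na(db)) 0 else db
      x[v, ] <- x[v, ] + (b + db * isCase) * x[pa, ]
    }
    if (v %in% names(perturbed_nodes))
      x[v, isCase] <- x[v, isCase] + perturbed_nodes[[v]]
  }
  truth <- list(
    edges = data.frame(parent = el[, 1L], child = el[, 2L],
                       beta = unname(true_betas[keys]),
                       stringsAsFactors = FALSE),
    perturbed_nodes = perturbed_nodes,
    perturbed_edges = perturbed_edges)
  list(expression = x, groups = grp, truth = truth)
}

#' Draw negative-binomial counts from latent log-expression
#'
#' Counts for gene g in sample j are drawn with mean
#' `mu = size_factor[j] * exp(latent[g, j])` and variance
#' `mu + dispersion * mu^2` (Poisson when `dispersion = 0`).
#'
#' @param latent gene x sample matrix of log-scale means
#' @param size_factors positive per-sample scaling
#' @param nb_dispersion alpha >= 0
#' @param seed integer seed
#' @return integer count matrix of the same shape
#' @export
genCounts <- function(latent, size_factors, nb_dispersion = 0, seed = 1L) {
  .stopIf(any(!is.finite(latent)), "latent values must be finite")
  .stopIf(any(size_factors <= 0), "size factors must be positive")
  .stopIf(nb_dispersion < 0, "dispersion must be >= 0")
  .stopIf(length(size_factors) != ncol(latent),
          "need one size factor per sample")
  set.seed(.substream(seed, "genCounts"))
  mu <- sweep(exp(latent), 2L, size_factors, `*`)
  k <- if (nb_dispersion == 0)
    stats::rpois(length(mu), mu)
  else
    stats::rnbinom(length(mu), size = 1 / nb_dispersion, mu = mu)
  matrix(as.integer(k), nrow = nrow(latent), dimnames = dimnames(latent))
}

#' Generate proportional-hazards survival outcomes
#'
#' Event times are exponential with hazard
#' `h0 * exp(sum_g beta_g * x_g)`; censoring times are uniform on
#' `(0, censor_max)`; the event flag is 1 when the event precedes censoring.
#'
#' @param expression gene x sample matrix
#' @param surv_beta named numeric, gene -> log-hazard coefficient
#' @param censor_max positive upper censoring bound
#' @param baseline_hazard h0 (default 0.1)
#' @param seed integer seed
#' @return data.frame: `sample_id`, `time`, `event`
#' @export
genSurvival <- function(expression, surv_beta, censor_max,
                        baseline_hazard = 0.1, seed = 1L) {
  .stopIf(censor_max <= 0, "censor_max must be positive")
  .stopIf(!all(names(surv_beta) %in% rownames(expression)),
          "surv_beta genes must be present in the expression matrix")
  set.seed(.substream(seed, "genSurvival"))
  n <- ncol(expression)
  lp <- if (length(surv_beta))
    drop(crossprod(expression[names(surv_beta), , drop = FALSE], surv_beta))
  else rep(0, n)
  h <- baseline_hazard * exp(lp)
  tev <- stats::rexp(n, rate = h)
  cens <- stats::runif(n, 0, censor_max)
  data.frame(sample_id = colnames(expression),
             time = pmin(tev, cens),
             event = as.integer(tev <= cens),
             stringsAsFactors = FALSE)
}

#' Select a deterministic gene panel
#'
#' @param genes character vector
#' @param panel_fraction fraction in \[0, 1\]; the panel size is
#'   `floor(panel_fraction * length(genes))`
#' @param seed integer seed
#' @return character vector of panel genes
#' @export
genPanel <- function(genes, panel_fraction, seed = 1L) {
  .stopIf(panel_fraction < 0 || panel_fraction > 1,
          "panel_fraction must lie in [0, 1]")
  set.seed(.substream(seed, "genPanel"))
  k <- floor(panel_fraction * length(genes))
  sort(sample(genes, k))
}

#' Split a DAG into overlapping pathway graphs
#'
#' Assigns every DAG edge to one of `n_pathways` pathways at random, so the
#' pathway union reconstructs the DAG exactly; each pathway's node set is the
#' endpoints of its edges.
#'
#' @param dag directed `igraph`
#' @param n_pathways number of pathways
#' @param seed integer seed
#' @return named list of directed `igraph` pathway graphs
#' @export
genPathways <- function(dag, n_pathways = 6L, seed = 1L) {
  el <- igraph::as_edgelist(dag, names = TRUE)
  .stopIf(nrow(el) == 0L, "DAG has no edges to distribute")
  set.seed(.substream(seed, "genPathways"))
  n_pathways <- min(n_pathways, nrow(el))
  assign <- sample(rep_len(seq_len(n_pathways), nrow(el)))
  out <- lapply(seq_len(n_pathways), function(k) {
    sub <- el[assign == k, , drop = FALSE]
    igraph::graph_from_edgelist(sub, directed = TRUE)
  })
  names(out) <- sprintf("pathway_%02d", seq_len(n_pathways))
  out
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with substreams of the master seed and returns all
#' pipeline inputs plus the planted ground truth: a counts
#' `SummarizedExperiment` with sample metadata, the gene panel, the pathway
#' collection, the survival table, and the latent expression.
#'
#' @param config a [simConfig()] list
#' @return list of class `SyntheticStudy` with elements `se`, `panel`,
#'   `pathways`, `survival`, `latent`, `groups`, `truth`, `config`
#' @export
simulateStudy <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  seed <- config$seed
  dag <- .genDagCommunities(config$dag_nodes, config$n_communities,
                            config$dag_p_in, config$dag_edge_prob,
                            seed)
  el <- igraph::as_edgelist(dag, names = TRUE)
  keys <- .edgeKey(el[, 1L], el[, 2L])
  set.seed(.substream(seed, "trueBetas"))
  betas <- stats::setNames(
    sample(c(-1, 1), length(keys), replace = TRUE) *
      stats::runif(length(keys), config$beta_range[1], config$beta_range[2]),
    keys)
  nodes <- igraph::V(dag)$name
  set.seed(.substream(seed, "perturbations"))
  pn <- sort(sample(nodes, min(config$n_perturbed_nodes, length(nodes))))
  perturbed_nodes <- stats::setNames(rep(config$delta, length(pn)), pn)
  pe <- sample(keys, min(config$n_perturbed_edges, length(keys)))
  perturbed_edges <- stats::setNames(rep(config$dbeta, length(pe)), pe)

  sim <- genTwoGroupExpression(dag, betas, perturbed_nodes, perturbed_edges,
                               config$n_case, config$n_control, seed)
  n <- config$n_case + config$n_control

  # background genes: iid noise, a fraction with a planted case shift
  n_bg <- config$n_genes - config$dag_nodes
  set.seed(.substream(seed, "background"))
  bg_names <- sprintf("BG%04d", seq_len(n_bg))
  bg <- matrix(stats::rnorm(n_bg * n), nrow = n_bg,
               dimnames = list(bg_names, colnames(sim$expression)))
  n_bg_de <- floor(config$frac_de_background * n_bg)
  bg_de <- sort(sample(bg_names, n_bg_de))
  bg[bg_de, sim$groups == "case"] <-
    bg[bg_de, sim$groups == "case"] + config$bg_shift
  latent_std <- rbind(sim$expression, bg)

  set.seed(.substream(seed, "baselines"))
  base_mu <- stats::runif(nrow(latent_std), config$baseline_logmean_range[1],
                          config$baseline_logmean_range[2])
  sf_true <- exp(stats::rnorm(n, 0, 0.15))
  sf_true <- sf_true / exp(mean(log(sf_true)))      # geometric mean 1
  # latent scale is natural-log expression, so a planted node shift delta
  # lands in the counts as a log2 fold change of exactly delta / ln 2
  latent <- latent_std + base_mu
  counts <- genCounts(latent, sf_true, config$nb_dispersion, seed)

  set.seed(.substream(seed, "metadata"))
  meta <- S4Vectors::DataFrame(
    sample_id = colnames(counts),
    group = sim$groups,
    sex = factor(sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))),
    grade = factor(sample(1:4, n, replace = TRUE,
                          prob = c(0.12, 0.31, 0.41, 0.16))),
    library_size = round(stats::runif(n, config$library_size_range[1],
                                      config$library_size_range[2])))
  rownames(meta) <- meta$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = meta)

  panel <- genPanel(rownames(counts), config$panel_fraction, seed)
  # make sure perturbed network genes are represented on the panel, as the
  # study design intends the panel to capture the perturbed family
  panel <- sort(union(panel, pn))
  pathways <- genPathways(dag, config$n_pathways, seed)

  sg <- sort(sample(pn, min(config$surv_genes, length(pn))))
  surv_beta <- stats::setNames(rep(config$surv_beta_value, length(sg)), sg)
  survival <- genSurvival(latent_std, surv_beta, config$censor_max,
                          config$baseline_hazard, seed)

  truth <- list(
    dag_edges = sim$truth$edges,
    perturbed_nodes = as.list(perturbed_nodes),
    perturbed_edges = as.list(perturbed_edges),
    communities = stats::setNames(as.integer(igraph::V(dag)$community), nodes),
    size_factors = stats::setNames(sf_true, colnames(counts)),
    surv_beta = as.list(surv_beta),
    background_de = bg_de)
  structure(list(se = se, panel = panel, pathways = pathways,
                 survival = survival, latent = latent_std,
                 groups = sim$groups, dag = dag, truth = truth,
                 config = config),
            class = "SyntheticStudy")
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Writes counts (TSV, genes as rows), metadata (CSV), panel (TXT, one symbol
#' per line), pathways (GMT membership and per-pathway SIF edges), survival
#' (CSV), and the ground truth (JSON).
#'
#' @param study result of [simulateStudy()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
writeStudy <- function(study, dir) {
  stopifnot(inherits(study, "SyntheticStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(study$se, "counts")
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             panel = file.path(dir, "panel.txt"),
             gmt = file.path(dir, "pathways.gmt"),
             sif = file.path(dir, "pathways.sif"),
             survival = file.path(dir, "survival.csv"),
             truth = file.path(dir, "ground_truth.json"))
  cdf <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  .writeTsv(cdf, paths["counts"])
  meta <- as.data.frame(SummarizedExperiment::colData(study$se))
  utils::write.csv(meta, paths["metadata"], row.names = FALSE, quote = FALSE)
  writeLines(study$panel, paths["panel"])
  gmt <- vapply(names(study$pathways), function(nm)
    paste(c(nm, "synthetic", sort(igraph::V(study$pathways[[nm]])$name)),
          collapse = "\t"), character(1))
  writeLines(gmt, paths["gmt"])
  sif <- do.call(rbind, lapply(names(study$pathways), function(nm) {
    e <- igraph::as_edgelist(study$pathways[[nm]], names = TRUE)
    data.frame(source = e[, 1L], relation = "directs", target = e[, 2L],
               pathway = nm, stringsAsFactors = FALSE)
  }))
  .writeTsv(sif, paths["sif"])
  utils::write.csv(study$survival, paths["survival"], row.names = FALSE,
                   quote = FALSE)
  truth <- study$truth
  truth$size_factors <- as.list(truth$size_factors)
  truth$communities <- as.list(truth$communities)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
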