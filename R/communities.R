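#' Walktrap community detection
#'
#' Runs the random-walk (walktrap) agglomerative community algorithm on the
#' graph treated as undirected and unweighted for topology, returning the
#' merge-level partition that maximizes Newman modularity. Isolated nodes
#' become singleton communities; disconnected components are handled
#' independently by the algorithm.
#'
#' @param graph an `igraph` (direction ignored); non-empty
#' @param t random-walk length (default 4)
#' @return a [CommunityPartition-class]
#' @export
walktrapCommunities <- function(graph, t = 4L) {
  .stopIf(igraph::vcount(graph) == 0L, "graph is empty")
  .stopIf(t < 1, "walk length t must be >= 1")
  ug <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  wt <- igraph::cluster_walktrap(ug, steps = t, weights = NULL)
  memb <- stats::setNames(as.integer(igraph::membership(wt)),
                          igraph::V(ug)$name)
  Q <- if (igraph::ecount(ug) > 0) graphModularity(ug, memb) else NA_real_
  methods::new("CommunityPartition", membership = memb, modularity = Q,
               steps = as.integer(t))
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \sum_c [ m_c/m - (d_c/2m)^2 ]} on the undirected simple graph,
#' where m is the edge count, m_c the intra-community edges, and d_c the sum
#' of degrees in community c.
#'
#' @param graph an `igraph` (treated as undirected simple); must have edges
#' @param membership named vector gene -> community covering all nodes
#' @return numeric Q in \[-0.5, 1\]
#' @export
graphModularity <- function(graph, membership) {
  ug <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  .stopIf(igraph::ecount(ug) == 0L, "modularity undefined on an edgeless graph")
  nodes <- igraph::V(ug)$name
  .stopIf(!all(nodes %in% names(membership)),
          "membership must cover every node")
  igraph::modularity(ug, as.integer(factor(membership[nodes])))
}

#' Community overlap with a reduced gene set
#'
#' One row per community: its size, the intersection with the reduced set,
#' and the intersection percentage rounded to the nearest integer (half away
#' from zero). Rows are sorted by percentage descending.
#'
#' @param partition a [CommunityPartition-class] or named membership vector
#' @param reduced_genes character vector (the reduced-graph gene set)
#' @return data.frame: `community`, `size`, `intersection`, `percentage`
#' @export
overlapSummary <- function(partition, reduced_genes) {
  memb <- if (methods::is(partition, "CommunityPartition"))
    partition@membership else partition
  comm <- split(names(memb), memb)
  out <- data.frame(
    community = names(comm),
    size = lengths(comm),
    intersection = vapply(comm, function(g)
      length(intersect(g, reduced_genes)), integer(1)),
    stringsAsFactors = FALSE)
  out$percentage <- as.integer(.roundHalfUp(100 * out$intersection / out$size))
  out <- out[order(-out$percentage, out$community), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when sampling the community's genes from
#' the universe without replacement; Benjamini-Hochberg adjusted across
#' sets.
#'
#' @param community_genes character vector (must lie within the universe)
#' @param gene_sets named list of character vectors (each within the
#'   universe)
#' @param universe character vector of all considered genes
#' @return data.frame: `set`, `overlap`, `set_size`, `p`, `padj`
#' @export
oraHypergeometric <- function(community_genes, gene_sets, universe) {
  .stopIf(length(universe) == 0L, "universe is empty")
  .stopIf(!all(community_genes %in% universe),
          "community genes must lie within the universe")
  N <- length(unique(universe))
  n <- length(unique(community_genes))
  rows <- lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(gene_sets[[nm]], community_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- .bh(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
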