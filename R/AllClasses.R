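#' @import methods
#' @importFrom igraph is_igraph vcount ecount gorder V E degree is_connected
NULL

#' Steiner tree (or forest) connecting seed genes
#'
#' Result of [kouSteiner()]: an acyclic subgraph of the weighted interactome
#' connecting the terminal (seed) genes through connector genes, one tree per
#' connected component that contains terminals.
#'
#' @slot graph undirected weighted `igraph`; acyclic unless the closure
#'   option re-added interactome edges among tree nodes
#' @slot terminals seed genes present in the tree
#' @slot connectors non-seed tree nodes
#' @slot weight total edge weight of the tree
#' @slot nComponents number of trees in the forest
#' @slot closed logical; `TRUE` when interactome edges among tree nodes were
#'   re-added (the graph may then contain cycles)
#' @exportClass SteinerTree
setClass("SteinerTree",
  slots = c(graph = "ANY", terminals = "character", connectors = "character",
            weight = "numeric", nComponents = "integer", closed = "logical"))

setValidity("SteinerTree", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  nodes <- igraph::V(g)$name
  if (!all(object@terminals %in% nodes)) return("terminals must be tree nodes")
  if (length(intersect(object@terminals, object@connectors)) > 0L)
    return("terminals and connectors must be disjoint")
  if (!setequal(c(object@terminals, object@connectors), nodes))
    return("terminals + connectors must partition the node set")
  if (!object@closed) {
    # forest: |E| = |V| - #components
    comp <- igraph::components(g)$no
    if (igraph::ecount(g) != igraph::vcount(g) - comp)
      return("graph is not a forest")
    deg <- igraph::degree(g)
    leaves <- names(deg)[deg <= 1L & igraph::vcount(g) > 1L]
    if (!all(leaves %in% object@terminals) && igraph::vcount(g) > 1L)
      return("every leaf must be a terminal")
  }
  TRUE
})

#' Recursive Gaussian SEM over a DAG
#'
#' A directed acyclic model in which each gene is a linear function of its
#' parent genes plus Gaussian noise. `B[child, parent]` holds the edge
#' coefficient; `Psi` the residual variances. The implied covariance is
#' \eqn{(I-B)^{-1} \Psi (I-B)^{-T}}.
#'
#' @slot order topological order of the nodes
#' @slot B edge-coefficient matrix, strictly triangular under `order`
#' @slot Psi named per-node residual variance, all positive
#' @slot edges data.frame with one row per retained edge: `child`, `parent`,
#'   `beta`, `se`, `z`, `p`, `padj`
#' @slot tau the sparsity threshold that produced the model (`NA` when not
#'   grid-derived)
#' @slot label model label, e.g. `"case"`, `"control"`, `"overall"`
#' @exportClass DagModel
setClass("DagModel",
  slots = c(order = "character", B = "matrix", Psi = "numeric",
            edges = "data.frame", tau = "numeric", label = "character"))

setValidity("DagModel", function(object) {
  p <- length(object@order)
  if (!all(dim(object@B) == c(p, p))) return("B must be p x p")
  if (!identical(rownames(object@B), object@order) ||
      !identical(colnames(object@B), object@order))
    return("B dimnames must equal the node order")
  # acyclicity: child may only depend on earlier nodes
  if (p > 0L) {
    upper <- object@B[upper.tri(object@B, diag = TRUE)]
    if (any(upper != 0)) return("B must be strictly lower triangular under order")
  }
  if (any(object@Psi <= 0)) return("residual variances must be positive")
  if (!setequal(names(object@Psi), object@order))
    return("Psi must be named by the node order")
  TRUE
})

#' Group-perturbation model (node shifts and edge differences)
#'
#' Joint case/control inference on a fitted DAG: per-node group effects
#' (disease status modeled as an exogenous parent of every gene) and
#' per-edge coefficient differences between the case and control models.
#'
#' @slot nodeEffects data.frame: `gene`, `estimate`, `se`, `z`, `p`, `padj`,
#'   `direction` (`"up"`/`"down"`)
#' @slot edgeDiffs data.frame: `child`, `parent`, `beta_case`, `beta_control`,
#'   `estimate` (the difference), `se`, `z`, `p`, `padj`
#' @slot caseModel,controlModel per-group [DagModel-class] fits (Models on
#'   case and control samples respectively)
#' @exportClass PerturbationModel
setClass("PerturbationModel",
  slots = c(nodeEffects = "data.frame", edgeDiffs = "data.frame",
            caseModel = "DagModel", controlModel = "DagModel"))

setValidity("PerturbationModel", function(object) {
  ne <- object@nodeEffects
  need <- c("gene", "estimate", "se", "z", "p", "padj", "direction")
  if (!all(need %in% names(ne))) return("nodeEffects missing columns")
  if (nrow(ne) && !all(ne$direction == ifelse(ne$estimate > 0, "up", "down")))
    return("direction must match the sign of the estimate")
  if (nrow(ne) && (any(ne$p < 0 | ne$p > 1, na.rm = TRUE)))
    return("p-values out of range")
  TRUE
})

#' Significant active-module subgraph
#'
#' @slot graph directed `igraph` of significant nodes and edges
#' @slot nodes data.frame of member nodes with `estimate`, `padj`, `sign`
#' @slot edges data.frame of member edges with `estimate`, `padj`, `sign`
#' @slot alpha significance threshold used (strict `<`)
#' @slot mode edge-selection mode, `"difference"` or `"group"`
#' @exportClass ActiveModule
setClass("ActiveModule",
  slots = c(graph = "ANY", nodes = "data.frame", edges = "data.frame",
            alpha = "numeric", mode = "character"))

#' Walktrap community partition
#'
#' @slot membership named integer vector, gene -> community id
#' @slot modularity Newman modularity Q of the partition
#' @slot steps random-walk length t
#' @exportClass CommunityPartition
setClass("CommunityPartition",
  slots = c(membership = "integer", modularity = "numeric", steps = "integer"))

setValidity("CommunityPartition", function(object) {
  if (is.null(names(object@membership))) return("membership must be named")
  if (length(object@modularity) == 1L && !is.na(object@modularity) &&
      (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9))
    return("modularity must lie in [-0.5, 1]")
  TRUE
})
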