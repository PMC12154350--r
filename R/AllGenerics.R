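#' @include AllClasses.R
NULL

#' @rdname SteinerTree-class
#' @param object,x a `SteinerTree`
#' @export
setGeneric("terminals", function(x) standardGeneric("terminals"))
#' @rdname SteinerTree-class
#' @export
setGeneric("connectors", function(x) standardGeneric("connectors"))
#' @rdname SteinerTree-class
#' @export
setGeneric("treeWeight", function(x) standardGeneric("treeWeight"))
#' @rdname SteinerTree-class
#' @export
setGeneric("moduleGraph", function(x) standardGeneric("moduleGraph"))

#' @rdname DagModel-class
#' @param x a `DagModel`
#' @export
setGeneric("dagOrder", function(x) standardGeneric("dagOrder"))
#' @rdname DagModel-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname DagModel-class
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname DagModel-class
#' @export
setGeneric("residualVariances", function(x) standardGeneric("residualVariances"))

#' @rdname PerturbationModel-class
#' @param x a `PerturbationModel`
#' @export
setGeneric("nodeEffects", function(x) standardGeneric("nodeEffects"))
#' @rdname PerturbationModel-class
#' @export
setGeneric("edgeDiffs", function(x) standardGeneric("edgeDiffs"))

#' @rdname CommunityPartition-class
#' @param x a `CommunityPartition`
#' @export
setGeneric("communityMembership", function(x) standardGeneric("communityMembership"))
#' @rdname CommunityPartition-class
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

setMethod("terminals", "SteinerTree", function(x) x@terminals)
setMethod("connectors", "SteinerTree", function(x) x@connectors)
setMethod("treeWeight", "SteinerTree", function(x) x@weight)
setMethod("moduleGraph", "SteinerTree", function(x) x@graph)
setMethod("moduleGraph", "ActiveModule", function(x) x@graph)

setMethod("dagOrder", "DagModel", function(x) x@order)
setMethod("edgeTable", "DagModel", function(x) x@edges)
setMethod("coefMatrix", "DagModel", function(x) x@B)
setMethod("residualVariances", "DagModel", function(x) x@Psi)

setMethod("nodeEffects", "PerturbationModel", function(x) x@nodeEffects)
setMethod("edgeDiffs", "PerturbationModel", function(x) x@edgeDiffs)

setMethod("communityMembership", "CommunityPartition", function(x) x@membership)
setMethod("modularityScore", "CommunityPartition", function(x) x@modularity)

setMethod("show", "SteinerTree", function(object) {
  cat(sprintf("SteinerTree: %d nodes (%d terminals, %d connectors), %d edges\n",
              igraph::vcount(object@graph), length(object@terminals),
              length(object@connectors), igraph::ecount(object@graph)))
  cat(sprintf("  total weight %.4g across %d component(s)%s\n", object@weight,
              object@nComponents,
              if (object@closed) " [closure edges re-added]" else ""))
})

setMethod("show", "DagModel", function(object) {
  cat(sprintf("DagModel '%s': %d nodes, %d edges", object@label,
              length(object@order), nrow(object@edges)))
  if (!is.na(object@tau)) cat(sprintf(" (tau = %.2f)", object@tau))
  cat("\n")
})

setMethod("show", "PerturbationModel", function(object) {
  cat(sprintf("PerturbationModel: %d node effects (%d with padj < 0.05), %d edge differences (%d with padj < 0.05)\n",
              nrow(object@nodeEffects), sum(object@nodeEffects$padj < 0.05),
              nrow(object@edgeDiffs),
              if (nrow(object@edgeDiffs)) sum(object@edgeDiffs$padj < 0.05) else 0L))
})

setMethod("show", "ActiveModule", function(object) {
  cat(sprintf("ActiveModule (alpha = %g, mode = %s): %d nodes, %d edges\n",
              object@alpha, object@mode, nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d nodes in %d communities (walk length %d), Q = %.3f\n",
              length(object@membership), length(unique(object@membership)),
              object@steps, object@modularity))
})
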