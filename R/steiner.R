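# Shortest paths and MSTs here are hand-rolled rather than delegated so that
# weight ties break by lexicographic node order, making the selected module
# reproducible; igraph serves as the independent cross-check in the tests.

# Dijkstra over an adjacency list with deterministic tie-breaking:
# among equal tentative distances the lexicographically smaller node is
# settled first, and equal-length paths keep the smaller predecessor.
.dijkstra <- function(adj, nodeNames, src) {
  n <- length(nodeNames)
  dist <- rep(Inf, n); pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[src] <- 0
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    dmin <- min(dist[cand])
    u <- cand[dist[cand] == dmin]
    if (length(u) > 1L) u <- u[order(nodeNames[u])][1L]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    nd <- dist[u] + nb$w
    for (k in seq_along(nb$to)) {
      v <- nb$to[k]
      if (done[v]) next
      if (nd[k] < dist[v]) {
        dist[v] <- nd[k]; pred[v] <- u
      } else if (nd[k] == dist[v] && !is.na(pred[v]) &&
                 nodeNames[u] < nodeNames[pred[v]]) {
        pred[v] <- u
      }
    }
  }
  list(dist = dist, pred = pred)
}

# Kruskal MST with edges sorted by (weight, lexicographic node pair)
.kruskal <- function(edges, n) {
  if (nrow(edges) == 0L) return(edges)
  a <- pmin(edges$ui, edges$vi); b <- pmax(edges$ui, edges$vi)
  ord <- order(edges$w, edges$ka, edges$kb)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- logical(nrow(edges))
  for (e in ord) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) { parent[ra] <- rb; keep[e] <- TRUE }
  }
  edges[keep, , drop = FALSE]
}

.edgeFrame <- function(g, nodeNames) {
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  .stopIf(is.null(w) && nrow(el) > 0, "graph edges must carry a weight attribute")
  if (nrow(el) == 0L)
    return(data.frame(u = character(0), v = character(0), w = numeric(0),
                      ui = integer(0), vi = integer(0),
                      ka = character(0), kb = character(0)))
  data.frame(u = el[, 1L], v = el[, 2L], w = w,
             ui = match(el[, 1L], nodeNames), vi = match(el[, 2L], nodeNames),
             ka = pmin(el[, 1L], el[, 2L]), kb = pmax(el[, 1L], el[, 2L]),
             stringsAsFactors = FALSE)
}

#' Steiner tree connecting seed genes (Kou-Markowsky-Berman)
#'
#' Approximates the minimum-weight tree spanning the terminal genes in a
#' positively weighted undirected graph: (1) build the metric closure of the
#' terminals via shortest paths, (2) take its minimum spanning tree,
#' (3) expand each closure edge into the underlying shortest path,
#' (4) take a minimum spanning tree of the expansion, (5) prune non-terminal
#' leaves. The cost is within `2(1 - 1/l)` of the optimum, where `l` is the
#' number of terminal leaves of the optimal tree. Ties in path lengths and
#' spanning-tree choices break by lexicographic node order, so the result is
#' deterministic. Terminals absent from the graph are dropped with a
#' warning; terminals spread over several connected components yield one
#' tree per component.
#'
#' @param graph undirected `igraph` with positive edge `weight`s (a directed
#'   graph is treated as undirected)
#' @param terminals character vector of seed genes (non-empty)
#' @param closure if `TRUE`, re-add all original graph edges among the tree
#'   nodes (the result may then contain cycles)
#' @return a [SteinerTree-class] object
#' @export
kouSteiner <- function(graph, terminals, closure = FALSE) {
  .stopIf(length(terminals) == 0L, "terminals must be non-empty")
  g <- igraph::as_undirected(graph, mode = "collapse",
                             edge.attr.comb = list(weight = "min", "ignore"))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min", "ignore"))
  w <- igraph::E(g)$weight
  .stopIf(igraph::ecount(g) > 0 && (is.null(w) || any(w <= 0)),
          "edge weights must be positive")
  nodeNames <- igraph::V(g)$name
  absent <- setdiff(terminals, nodeNames)
  if (length(absent)) {
    warning(sprintf("dropping %d terminal(s) absent from the graph: %s",
                    length(absent), paste(absent, collapse = ", ")))
    terminals <- setdiff(terminals, absent)
  }
  .stopIf(length(terminals) == 0L, "no terminal is present in the graph")
  terminals <- sort(unique(terminals))

  ef <- .edgeFrame(g, nodeNames)
  adj <- vector("list", length(nodeNames))
  if (nrow(ef)) {
    for (k in seq_len(nrow(ef))) {
      adj[[ef$ui[k]]] <- rbind(adj[[ef$ui[k]]],
                               data.frame(to = ef$vi[k], w = ef$w[k]))
      adj[[ef$vi[k]]] <- rbind(adj[[ef$vi[k]]],
                               data.frame(to = ef$ui[k], w = ef$w[k]))
    }
  }

  comp <- igraph::components(g)$membership
  tcomp <- split(terminals, comp[match(terminals, nodeNames)])
  if (length(tcomp) > 1L)
    message(sprintf("terminals span %d components; returning a forest",
                    length(tcomp)))

  treeEdges <- list(); treeNodes <- character(0)
  for (ts in tcomp) {
    if (length(ts) == 1L) { treeNodes <- c(treeNodes, ts); next }
    ti <- match(ts, nodeNames)
    sp <- lapply(ti, function(s) .dijkstra(adj, nodeNames, s))
    names(sp) <- ts
    # metric closure among terminals of this component
    cl <- do.call(rbind, lapply(seq_along(ts), function(i) {
      if (i == length(ts)) return(NULL)
      js <- (i + 1L):length(ts)
      data.frame(u = ts[i], v = ts[js], w = sp[[i]]$dist[ti[js]],
                 ui = i, vi = js, ka = pmin(ts[i], ts[js]),
                 kb = pmax(ts[i], ts[js]), stringsAsFactors = FALSE)
    }))
    clmst <- .kruskal(cl, length(ts))
    # expand closure edges into shortest paths
    pathEdges <- list()
    for (e in seq_len(nrow(clmst))) {
      src <- clmst$u[e]; cur <- match(clmst$v[e], nodeNames)
      pr <- sp[[src]]$pred
      while (!is.na(pr[cur])) {
        pathEdges[[length(pathEdges) + 1L]] <- c(pr[cur], cur)
        cur <- pr[cur]
      }
    }
    pe <- unique(do.call(rbind, pathEdges))
    sub <- ef[(ef$ui %in% pe[, 1L] | ef$ui %in% pe[, 2L]) &
              (ef$vi %in% pe[, 1L] | ef$vi %in% pe[, 2L]), , drop = FALSE]
    # keep exactly the expanded edges
    key <- paste(pmin(pe[, 1L], pe[, 2L]), pmax(pe[, 1L], pe[, 2L]))
    sub <- sub[paste(pmin(sub$ui, sub$vi), pmax(sub$ui, sub$vi)) %in% key, ,
               drop = FALSE]
    # MST of the expansion, then prune non-terminal leaves
    mst <- .kruskal(sub, length(nodeNames))
    repeat {
      deg <- table(c(mst$u, mst$v))
      leaves <- setdiff(names(deg)[deg == 1L], ts)
      if (!length(leaves)) break
      mst <- mst[!(mst$u %in% leaves | mst$v %in% leaves), , drop = FALSE]
    }
    treeEdges[[length(treeEdges) + 1L]] <- mst
    treeNodes <- c(treeNodes, unique(c(mst$u, mst$v)))
  }
  te <- if (length(treeEdges)) do.call(rbind, treeEdges)
        else data.frame(u = character(0), v = character(0), w = numeric(0))
  nodes <- sort(unique(c(treeNodes, terminals)))
  tg <- igraph::graph_from_data_frame(
    data.frame(from = te$u, to = te$v, weight = te$w), directed = FALSE,
    vertices = nodes)
  closed <- isTRUE(closure)
  if (closed) {
    extra <- ef[ef$u %in% nodes & ef$v %in% nodes, , drop = FALSE]
    have <- .undirKey(te$u, te$v)
    extra <- extra[!(.undirKey(extra$u, extra$v) %in% have), , drop = FALSE]
    if (nrow(extra))
      tg <- igraph::add_edges(tg, as.vector(rbind(extra$u, extra$v)),
                              weight = extra$w)
  }
  methods::new("SteinerTree", graph = tg, terminals = terminals,
               connectors = setdiff(nodes, terminals),
               weight = sum(igraph::E(tg)$weight),
               nComponents = length(tcomp), closed = closed)
}
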