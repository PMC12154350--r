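# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: igraph MST/enumeration for Steiner optima,
# explicit formula loops for modularity and SRMR, and direct closed forms.

# exact minimum Steiner tree by enumeration over connector subsets
bruteForceSteiner <- function(g, terminals) {
  stopifnot(igraph::is_connected(g))
  others <- setdiff(igraph::V(g)$name, terminals)
  best <- Inf; bestTrees <- list()
  for (k in 0:length(others)) {
    combs <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (extra in combs) {
      vs <- c(terminals, extra)
      sub <- igraph::induced_subgraph(g, vs)
      if (!igraph::is_connected(sub)) next
      mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
      w <- sum(igraph::E(mst)$weight)
      # prune non-terminal leaves of the MST
      repeat {
        deg <- igraph::degree(mst)
        drop <- names(deg)[deg <= 1 & !(igraph::V(mst)$name %in% terminals)]
        if (!length(drop)) break
        mst <- igraph::delete_vertices(mst, drop)
      }
      w <- sum(igraph::E(mst)$weight)
      if (w < best - 1e-12) { best <- w; bestTrees <- list(mst) }
      else if (abs(w - best) <= 1e-12) bestTrees <- c(bestTrees, list(mst))
    }
  }
  # maximum number of terminal leaves over the optimal trees (for the
  # 2(1 - 1/l) approximation bound)
  l <- max(vapply(bestTrees, function(tr) {
    deg <- igraph::degree(tr)
    sum(names(deg)[deg <= 1] %in% terminals)
  }, numeric(1)))
  list(opt = best, l = max(l, 2))
}

# random connected weighted graph for Steiner property tests
randomConnectedGraph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.1, 1), 3)
  g
}

# Newman modularity by explicit formula loop
bruteModularity <- function(g, memb) {
  ug <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  m <- igraph::ecount(ug)
  el <- igraph::as_edgelist(ug, names = TRUE)
  deg <- igraph::degree(ug)
  Q <- 0
  for (c in unique(memb)) {
    vs <- names(memb)[memb == c]
    mc <- sum(el[, 1] %in% vs & el[, 2] %in% vs)
    dc <- sum(deg[vs])
    Q <- Q + mc / m - (dc / (2 * m))^2
  }
  Q
}

# SRMR by path-tracing: implied covariance from the nilpotent series
# I + B + B^2 + ..., residuals accumulated in an explicit double loop
pathTracingSRMR <- function(B, Psi, x) {
  p <- nrow(B)
  Tot <- diag(p)
  Bk <- diag(p)
  for (k in seq_len(p)) {
    Bk <- Bk %*% B
    Tot <- Tot + Bk
  }
  Sigma <- Tot %*% diag(Psi, nrow = p) %*% t(Tot)
  Rho <- stats::cov2cor(Sigma)
  S <- stats::cor(t(x))
  acc <- 0; cnt <- 0
  for (i in seq_len(p)) for (j in seq_len(i)) {
    acc <- acc + (S[i, j] - Rho[i, j])^2
    cnt <- cnt + 1
  }
  sqrt(acc / cnt)
}

# random DagModel (triangular B) plus data drawn from it
randomDagModel <- function(p = 5, n = 40) {
  ord <- sprintf("g%d", seq_len(p))
  B <- matrix(0, p, p, dimnames = list(ord, ord))
  for (i in seq_len(p)) for (j in seq_len(i - 1))
    if (stats::runif(1) < 0.5) B[i, j] <- round(stats::runif(1, -0.8, 0.8), 2)
  Psi <- stats::setNames(round(stats::runif(p, 0.5, 1.5), 2), ord)
  x <- matrix(stats::rnorm(p * n), p, n, dimnames = list(ord, NULL))
  edges <- which(B != 0, arr.ind = TRUE)
  ed <- data.frame(child = ord[edges[, 1]], parent = ord[edges[, 2]],
                   beta = B[edges], se = 1, z = 0, p = 1, padj = 1,
                   stringsAsFactors = FALSE)
  model <- methods::new("DagModel", order = ord, B = B, Psi = Psi,
                        edges = ed, tau = NA_real_, label = "synthetic")
  list(model = model, x = x)
}

# adjusted Rand index (Hubert-Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

# planted membership construction matching given community sizes and
# reduced-set intersections
plantedOverlapFixture <- function(sizes, intersections) {
  stopifnot(length(sizes) == length(intersections))
  memb <- integer(0); reduced <- character(0)
  for (i in seq_along(sizes)) {
    genes <- sprintf("c%02d_g%02d", i, seq_len(sizes[i]))
    memb <- c(memb, stats::setNames(rep(i, sizes[i]), genes))
    reduced <- c(reduced, genes[seq_len(intersections[i])])
  }
  list(membership = memb, reduced = reduced)
}

# random signed edge coefficients named "parent|child" for a DAG
.trueBetasFor <- function(dag, seed = 1, lo = 0.4, hi = 0.8) {
  el <- igraph::as_edgelist(dag, names = TRUE)
  set.seed(seed)
  stats::setNames(
    sample(c(-1, 1), nrow(el), replace = TRUE) *
      stats::runif(nrow(el), lo, hi),
    paste(el[, 1], el[, 2], sep = "|"))
}
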