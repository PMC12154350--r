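# Node-wise constrained Gaussian graphical modeling over a DAG: lasso edge
# screening on a sparsity grid, per-group recursive OLS fits, SRMR scoring,
# and joint group-perturbation inference.

# per-node OLS with classical SEs; X has no intercept column (added here)
.olsNode <- function(y, X) {
  Xm <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xm, y)
  res <- fit$residuals
  dfres <- length(y) - ncol(Xm)
  s2 <- if (dfres > 0) sum(res^2) / dfres else NA_real_
  XtXinv <- tryCatch(chol2inv(chol(crossprod(Xm))), error = function(e) NULL)
  se <- if (is.null(XtXinv)) rep(NA_real_, ncol(Xm)) else sqrt(s2 * diag(XtXinv))
  list(coef = fit$coefficients, se = se, rss = sum(res^2), n = length(y))
}

#' Orient an undirected module scaffold and produce a topological order
#'
#' Each tree edge is oriented by its direction in the reference interactome
#' when that is unambiguous (exactly one of u->v, v->u present); reciprocal
#' or unknown edges are resolved root-outward from the highest-degree
#' terminal (ties alphabetical). A tree admits no directed cycle under any
#' orientation, so the result is a DAG; its topological order is returned.
#'
#' @param tree undirected acyclic `igraph` (or a [SteinerTree-class])
#' @param reference directed `igraph` providing edge directions
#' @param terminals optional terminal set used to pick the root (defaults to
#'   the `SteinerTree` terminals, else all nodes)
#' @return list with `graph` (oriented directed `igraph`) and `order`
#'   (topological node order)
#' @export
orientAndOrder <- function(tree, reference = NULL, terminals = NULL) {
  if (methods::is(tree, "SteinerTree")) {
    if (is.null(terminals)) terminals <- terminals(tree)
    tree <- moduleGraph(tree)
  }
  ug <- igraph::as_undirected(tree, mode = "collapse")
  el <- igraph::as_edgelist(ug, names = TRUE)
  nodes <- igraph::V(ug)$name
  refKeys <- if (!is.null(reference))
    .edgeKey(igraph::as_edgelist(reference, names = TRUE)[, 1L],
             igraph::as_edgelist(reference, names = TRUE)[, 2L])
  else character(0)
  if (is.null(terminals) || !length(intersect(terminals, nodes)))
    terminals <- nodes
  deg <- igraph::degree(ug)
  cand <- intersect(terminals, nodes)
  root <- cand[order(-deg[cand], cand)][1L]

  from <- character(nrow(el)); to <- character(nrow(el))
  unknown <- logical(nrow(el))
  for (k in seq_len(nrow(el))) {
    u <- el[k, 1L]; v <- el[k, 2L]
    fwd <- .edgeKey(u, v) %in% refKeys
    rev <- .edgeKey(v, u) %in% refKeys
    if (xor(fwd, rev)) {
      from[k] <- if (fwd) u else v
      to[k] <- if (fwd) v else u
    } else unknown[k] <- TRUE
  }
  if (any(unknown)) {
    # BFS depth from the root (per component; foreign components rooted at
    # their alphabetically first node), orienting unknown edges outward
    depth <- rep(NA_integer_, length(nodes)); names(depth) <- nodes
    ordBfs <- igraph::bfs(ug, root = root, unreachable = TRUE,
                          order = TRUE, dist = TRUE)
    depth[] <- ordBfs$dist[nodes]
    for (k in which(unknown)) {
      u <- el[k, 1L]; v <- el[k, 2L]
      pair <- c(u, v)[order(depth[c(u, v)], c(u, v))]
      from[k] <- pair[1L]; to[k] <- pair[2L]
    }
  }
  dg <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = sort(nodes))
  ord <- igraph::V(dg)$name[as.integer(igraph::topo_sort(dg))]
  list(graph = dg, order = ord)
}

# internal: lasso support of y on X (matrix with >= 1 column), BIC lambda
.lassoSupport <- function(y, X) {
  if (ncol(X) == 1L) {
    f <- .olsNode(y, X)
    return(if (abs(f$coef[2L]) > 1e-8) 1L else integer(0))
  }
  fit <- glmnet::glmnet(X, y, standardize = FALSE, intercept = TRUE)
  pred <- stats::predict(fit, X)
  n <- length(y)
  rss <- colSums((pred - y)^2)
  bic <- n * log(pmax(rss / n, 1e-12)) + fit$df * log(n)
  beta <- fit$beta[, which.min(bic)]
  which(abs(beta) > 1e-8)
}

#' Node-wise lasso DAG search over a sparsity grid
#'
#' For each node in the topological order, regresses it on all predecessor
#' nodes with an L1 penalty (lambda by BIC), refits ordinary least squares on
#' the selected support, and — for each grid value tau — retains edges whose
#' refit standardized coefficient exceeds tau in absolute value, refitting on
#' the thresholded support so each candidate carries post-selection
#' estimates with classical asymptotic standard errors. Expression should be
#' standardized per gene so the coefficients live on the scale of the grid.
#'
#' @param x gene x sample matrix, standardized per gene
#' @param node_order topological order covering the genes to model
#' @param beta_grid vector of thresholds (default 0.05 to 0.15 by 0.01)
#' @return list of candidate [DagModel-class] objects, one per grid value
#' @export
dagNodewiseLasso <- function(x, node_order,
                             beta_grid = seq(0.05, 0.15, by = 0.01)) {
  .stopIf(ncol(x) < 3, "need at least 3 samples")
  .stopIf(!all(node_order %in% rownames(x)),
          "node_order contains genes missing from the matrix")
  xt <- t(x[node_order, , drop = FALSE])     # samples x genes
  p <- length(node_order)
  # lasso screening once per node; thresholding then varies with tau
  support <- vector("list", p); betaHat <- vector("list", p)
  for (i in seq_len(p)) {
    if (i == 1L) { support[[i]] <- character(0); betaHat[[i]] <- numeric(0); next }
    preds <- node_order[seq_len(i - 1L)]
    sel <- .lassoSupport(xt[, node_order[i]], xt[, preds, drop = FALSE])
    sel <- preds[sel]
    if (length(sel)) {
      f <- .olsNode(xt[, node_order[i]], xt[, sel, drop = FALSE])
      betaHat[[i]] <- stats::setNames(f$coef[-1L], sel)
    } else betaHat[[i]] <- numeric(0)
    support[[i]] <- sel
  }
  lapply(beta_grid, function(tau) {
    edges <- list(); B <- matrix(0, p, p, dimnames = list(node_order, node_order))
    Psi <- stats::setNames(numeric(p), node_order)
    for (i in seq_len(p)) {
      keep <- names(betaHat[[i]])[abs(betaHat[[i]]) > tau]
      y <- xt[, node_order[i]]
      if (length(keep)) {
        f <- .olsNode(y, xt[, keep, drop = FALSE])
        b <- f$coef[-1L]; se <- f$se[-1L]
        B[node_order[i], keep] <- b
        Psi[i] <- f$rss / (f$n - 1)
        edges[[length(edges) + 1L]] <- data.frame(
          child = node_order[i], parent = keep, beta = unname(b),
          se = unname(se), z = unname(b / se),
          p = 2 * stats::pnorm(-abs(unname(b / se))),
          stringsAsFactors = FALSE)
      } else Psi[i] <- sum((y - mean(y))^2) / (length(y) - 1)
    }
    ed <- if (length(edges)) do.call(rbind, edges)
          else data.frame(child = character(0), parent = character(0),
                          beta = numeric(0), se = numeric(0), z = numeric(0),
                          p = numeric(0))
    ed$padj <- .bh(ed$p)
    methods::new("DagModel", order = node_order, B = B, Psi = Psi,
                 edges = ed, tau = tau, label = "candidate")
  })
}

#' Pick the optimal DAG from grid candidates
#'
#' Computes the SRMR of every candidate on the data and returns the sparsest
#' candidate whose SRMR is within 0.01 of the minimum — the balance between
#' model adjustment and graph sparsity.
#'
#' @param candidates list of [DagModel-class] objects
#' @param x gene x sample matrix the models were fitted on
#' @param srmr_slack allowed SRMR excess over the best (default 0.01)
#' @return the selected [DagModel-class] (slot `tau` records the winning
#'   threshold)
#' @export
selectOptimalDag <- function(candidates, x, srmr_slack = 0.01) {
  .stopIf(length(candidates) == 0L, "no candidates")
  fits <- vapply(candidates, function(m) srmr(m, x)$srmr, numeric(1))
  sizes <- vapply(candidates, function(m) nrow(m@edges), integer(1))
  ok <- which(fits <= min(fits) + srmr_slack)
  pick <- ok[order(sizes[ok], fits[ok])][1L]
  out <- candidates[[pick]]
  out@label <- "optimal"
  out
}

#' Fit the recursive SEM on one sample group
#'
#' Ordinary least squares of each node on its DAG parents within a single
#' group; returns edge coefficients B, residual variances Psi, classical
#' standard errors, two-sided z-tests of H0: beta = 0, and BH-adjusted
#' p-values across edges. Residual variances use the n-1 denominator so a
#' saturated model reproduces the sample covariance exactly.
#'
#' @param dag a [DagModel-class] (its edges define the structure) or a
#'   directed `igraph`
#' @param x gene x sample matrix for the group's samples
#' @param label model label stored in the result
#' @return a fitted [DagModel-class]
#' @export
fitGroupModel <- function(dag, x, label = "group") {
  st <- .dagStructure(dag)
  missing <- setdiff(st$order, rownames(x))
  .stopIf(length(missing) > 0, "gene(s) missing from the matrix: %s",
          paste(missing, collapse = ", "))
  xt <- t(x[st$order, , drop = FALSE])
  zeroVar <- names(which(apply(xt, 2L, stats::var) == 0))
  .stopIf(length(zeroVar) > 0, "zero-variance node(s): %s",
          paste(zeroVar, collapse = ", "))
  p <- length(st$order)
  B <- matrix(0, p, p, dimnames = list(st$order, st$order))
  Psi <- stats::setNames(numeric(p), st$order)
  edges <- list()
  for (i in seq_len(p)) {
    v <- st$order[i]; pa <- st$parents[[v]]
    y <- xt[, v]
    if (length(pa)) {
      .stopIf(nrow(xt) < length(pa) + 2,
              "node %s: need at least #parents + 2 samples", v)
      f <- .olsNode(y, xt[, pa, drop = FALSE])
      b <- f$coef[-1L]; se <- f$se[-1L]
      B[v, pa] <- b
      Psi[i] <- f$rss / (f$n - 1)
      edges[[length(edges) + 1L]] <- data.frame(
        child = v, parent = pa, beta = unname(b), se = unname(se),
        z = unname(b / se), p = 2 * stats::pnorm(-abs(unname(b / se))),
        stringsAsFactors = FALSE)
    } else Psi[i] <- stats::var(y)
  }
  ed <- if (length(edges)) do.call(rbind, edges)
        else data.frame(child = character(0), parent = character(0),
                        beta = numeric(0), se = numeric(0), z = numeric(0),
                        p = numeric(0))
  ed$padj <- .bh(ed$p)
  rownames(ed) <- NULL
  methods::new("DagModel", order = st$order, B = B, Psi = Psi, edges = ed,
               tau = NA_real_, label = label)
}

# normalize DagModel / igraph input into (order, parents)
.dagStructure <- function(dag) {
  if (methods::is(dag, "DagModel")) {
    parents <- lapply(dag@order, function(v)
      dag@edges$parent[dag@edges$child == v])
    names(parents) <- dag@order
    return(list(order = dag@order, parents = parents))
  }
  .stopIf(!igraph::is_igraph(dag), "dag must be a DagModel or igraph")
  ord <- igraph::V(dag)$name[as.integer(igraph::topo_sort(dag))]
  parents <- lapply(ord, function(v)
    igraph::V(dag)$name[igraph::neighbors(dag, v, mode = "in")])
  names(parents) <- ord
  list(order = ord, parents = parents)
}

#' Joint group-perturbation model (node shifts and edge differences)
#'
#' Two-step procedure. Step 1: each node is regressed on its DAG parents
#' plus the group indicator; the group coefficient is the node's
#' perturbation (case minus control shift given parents), tested two-sided
#' and BH-adjusted across nodes. Step 2: the per-group models are fitted on
#' cases and controls separately and each edge's coefficient difference is
#' tested with \eqn{z = (\beta_{case} - \beta_{control}) /
#' \sqrt{SE_{case}^2 + SE_{control}^2}}, BH-adjusted across edges.
#'
#' @param dag [DagModel-class] or directed `igraph` defining the structure
#' @param x gene x sample matrix (both groups)
#' @param groups factor/character `case`/`control`
#' @return a [PerturbationModel-class]
#' @export
fitPerturbationModel <- function(dag, x, groups) {
  st <- .dagStructure(dag)
  groups <- as.character(groups)
  grp <- as.numeric(groups == "case")
  .stopIf(sum(grp) < 2 || sum(1 - grp) < 2, "each group needs >= 2 samples")
  xt <- t(x[st$order, , drop = FALSE])
  ne <- lapply(st$order, function(v) {
    pa <- st$parents[[v]]
    X <- cbind(group = grp,
               if (length(pa)) xt[, pa, drop = FALSE])
    f <- .olsNode(xt[, v], X)
    est <- f$coef[2L]; se <- f$se[2L]
    data.frame(gene = v, estimate = unname(est), se = unname(se),
               z = unname(est / se), p = 2 * stats::pnorm(-abs(unname(est / se))),
               stringsAsFactors = FALSE)
  })
  ne <- do.call(rbind, ne)
  ne$padj <- .bh(ne$p)
  ne$direction <- ifelse(ne$estimate > 0, "up", "down")

  mA <- fitGroupModel(dag, x[, groups == "case", drop = FALSE], "case")
  mB <- fitGroupModel(dag, x[, groups == "control", drop = FALSE], "control")
  ea <- mA@edges; eb <- mB@edges
  key <- .edgeKey(ea$parent, ea$child)
  stopifnot(identical(key, .edgeKey(eb$parent, eb$child)))
  if (nrow(ea)) {
    diff <- ea$beta - eb$beta
    se <- sqrt(ea$se^2 + eb$se^2)
    z <- diff / se
    ed <- data.frame(child = ea$child, parent = ea$parent,
                     beta_case = ea$beta, beta_control = eb$beta,
                     estimate = diff, se = se, z = z,
                     p = 2 * stats::pnorm(-abs(z)),
                     stringsAsFactors = FALSE)
    ed$padj <- .bh(ed$p)
  } else {
    ed <- data.frame(child = character(0), parent = character(0),
                     beta_case = numeric(0), beta_control = numeric(0),
                     estimate = numeric(0), se = numeric(0), z = numeric(0),
                     p = numeric(0), padj = numeric(0))
  }
  methods::new("PerturbationModel", nodeEffects = ne, edgeDiffs = ed,
               caseModel = mA, controlModel = mB)
}

#' Standardized root mean square residual of a fitted DAG model
#'
#' Compares the observed correlations with those implied by
#' \eqn{\hat\Sigma = (I-B)^{-1} \Psi (I-B)^{-T}}:
#' \deqn{SRMR = \sqrt{\sum_{i \le j} (r_{ij} - \hat\rho_{ij})^2 / (p(p+1)/2)}}
#' Diagonal residuals are zero because Psi is fitted. Values below 0.10 are
#' conventionally considered adequate fit.
#'
#' @param model a [DagModel-class]
#' @param x gene x sample matrix containing the model's nodes
#' @return list with `srmr`, `label`, and the residual matrix
#' @export
srmr <- function(model, x) {
  ord <- model@order
  .stopIf(!all(ord %in% rownames(x)), "model nodes missing from the matrix")
  S <- stats::cor(t(x[ord, , drop = FALSE]))
  I <- diag(length(ord))
  Binv <- solve(I - model@B)
  Sigma <- Binv %*% diag(model@Psi, nrow = length(ord)) %*% t(Binv)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  .stopIf(min(ev) <= 0, "implied covariance is not positive definite")
  Rho <- stats::cov2cor(Sigma)
  res <- S - Rho
  p <- length(ord)
  val <- sqrt(sum(res[lower.tri(res, diag = TRUE)]^2) / (p * (p + 1) / 2))
  list(srmr = val, label = model@label, residuals = res)
}

#' Direct, indirect, and total effects between two genes
#'
#' The indirect effect of `source` on `target` is the sum over all directed
#' paths (excluding the direct edge) of the product of path coefficients;
#' computed via the nilpotent series \eqn{(I-B)^{-1} = I + B + B^2 + ...}.
#'
#' @param model a [DagModel-class]
#' @param source,target gene names in the model
#' @return list with `direct`, `indirect`, `total`
#' @export
indirectEffects <- function(model, source, target) {
  ord <- model@order
  .stopIf(!source %in% ord || !target %in% ord,
          "source and target must be model nodes")
  Tot <- solve(diag(length(ord)) - model@B) - diag(length(ord))
  dimnames(Tot) <- dimnames(model@B)
  direct <- model@B[target, source]
  total <- Tot[target, source]
  list(direct = direct, indirect = total - direct, total = total)
}

#' Extract the significant active module
#'
#' Nodes with perturbation `padj < alpha`; edges with `padj < alpha` either
#' in the case/control group models (`mode = "group"`: significant in
#' either) or in the case-minus-control difference test
#' (`mode = "difference"`). The inequality is strict.
#'
#' @param pm a [PerturbationModel-class]
#' @param alpha significance level in (0, 1)
#' @param mode `"difference"` (default) or `"group"`
#' @return an [ActiveModule-class]
#' @export
extractActiveModule <- function(pm, alpha = 0.05,
                                mode = c("difference", "group")) {
  mode <- match.arg(mode)
  .stopIf(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  ne <- pm@nodeEffects
  nodes <- ne[ne$padj < alpha, , drop = FALSE]
  nodes$sign <- ifelse(nodes$estimate > 0, 1L, -1L)
  if (mode == "difference") {
    ed <- pm@edgeDiffs
    edges <- ed[nrow(ed) > 0 & ed$padj < alpha, , drop = FALSE]
  } else {
    ea <- pm@caseModel@edges; eb <- pm@controlModel@edges
    sig <- (ea$padj < alpha) | (eb$padj < alpha)
    edges <- data.frame(child = ea$child, parent = ea$parent,
                        estimate = ea$beta, se = ea$se, z = ea$z,
                        p = ea$p, padj = pmin(ea$padj, eb$padj),
                        stringsAsFactors = FALSE)[sig, , drop = FALSE]
  }
  edges$sign <- if (nrow(edges)) ifelse(edges$estimate > 0, 1L, -1L) else integer(0)
  vs <- sort(unique(c(nodes$gene, edges$parent, edges$child)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$parent, to = edges$child), directed = TRUE,
    vertices = if (length(vs)) vs else character(0))
  rownames(nodes) <- rownames(edges) <- NULL
  methods::new("ActiveModule", graph = g, nodes = nodes, edges = edges,
               alpha = alpha, mode = mode)
}
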