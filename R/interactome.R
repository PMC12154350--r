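#' Build the pathway-union interactome
#'
#' Unions a collection of directed pathway graphs into one interactome.
#' Duplicate edges collapse to a single edge whose `provenance` attribute
#' lists every contributing pathway; self-loops are dropped.
#'
#' @param pathways named list of directed `igraph` objects (or data.frames
#'   with columns `source`, `target`)
#' @return a directed `igraph` with edge attribute `provenance`
#' @export
buildInteractome <- function(pathways) {
  .stopIf(length(pathways) == 0L, "pathway collection is empty")
  if (is.null(names(pathways)))
    names(pathways) <- sprintf("pathway_%02d", seq_along(pathways))
  els <- lapply(names(pathways), function(nm) {
    p <- pathways[[nm]]
    el <- if (igraph::is_igraph(p)) igraph::as_edgelist(p, names = TRUE)
          else as.matrix(p[, c("source", "target")])
    if (nrow(el) == 0L) return(NULL)
    data.frame(from = el[, 1L], to = el[, 2L], pathway = nm,
               stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, els)
  .stopIf(is.null(el) || nrow(el) == 0L, "pathway collection has no edges")
  el <- el[el$from != el$to, , drop = FALSE]
  key <- .edgeKey(el$from, el$to)
  prov <- split(el$pathway, key)
  uniq <- el[!duplicated(key), , drop = FALSE]
  singletons <- setdiff(
    unlist(lapply(pathways, function(p)
      if (igraph::is_igraph(p)) igraph::V(p)$name else NULL)),
    c(uniq$from, uniq$to))
  g <- igraph::graph_from_data_frame(uniq[, c("from", "to")], directed = TRUE,
    vertices = unique(c(uniq$from, uniq$to, singletons)))
  igraph::E(g)$provenance <- unname(prov[.edgeKey(uniq$from, uniq$to)])
  g
}

#' Nonparanormal (rank-Gaussian) transform
#'
#' Maps each gene's values through the standard normal quantile function at
#' `(rank - 0.5) / n`, with ties given their average rank. The output is
#' invariant to strictly increasing transforms of the input and has per-gene
#' mean approximately zero. Constant genes become all zeros with a warning.
#'
#' @param x gene x sample matrix (needs >= 3 samples)
#' @return transformed matrix of the same shape
#' @export
nonparanormalTransform <- function(x) {
  .stopIf(ncol(x) < 3, "nonparanormal transform needs at least 3 samples")
  n <- ncol(x)
  out <- t(apply(x, 1L, function(r) {
    if (stats::var(r) == 0) return(rep(0, n))
    stats::qnorm((rank(r, ties.method = "average") - 0.5) / n)
  }))
  dimnames(out) <- dimnames(x)
  if (any(apply(x, 1L, stats::var) == 0))
    warning("constant gene(s) mapped to all zeros")
  out
}

#' Two-group differential-correlation test for interactome edges
#'
#' For each edge (u, v), Pearson correlations are computed within cases and
#' controls, Fisher r-to-z transformed (`z = atanh(r)`), and compared with
#' \deqn{Z = (z_{case} - z_{control}) / \sqrt{1/(n_{case}-3) + 1/(n_{control}-3)}}
#' with a two-sided normal p-value. Correlations are clamped to |r| < 1.
#'
#' @param x gene x sample matrix (typically nonparanormal-transformed)
#' @param groups factor/character, `case`/`control`, each with n > 3
#' @param edges two-column matrix or data.frame of gene pairs
#' @return data.frame: `u`, `v`, `r_case`, `r_control`, `z_case`,
#'   `z_control`, `Z`, `p`
#' @export
edgeCorrelationTest <- function(x, groups, edges) {
  groups <- as.character(groups)
  n1 <- sum(groups == "case"); n2 <- sum(groups == "control")
  .stopIf(n1 <= 3 || n2 <= 3, "each group needs n > 3 for the r-to-z test")
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  missing <- setdiff(unique(c(edges)), rownames(x))
  .stopIf(length(missing) > 0, "gene(s) missing from the matrix: %s",
          paste(missing, collapse = ", "))
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  corOf <- function(sub) {
    ru <- sub[edges[, 1L], , drop = FALSE]
    rv <- sub[edges[, 2L], , drop = FALSE]
    ru <- ru - rowMeans(ru); rv <- rv - rowMeans(rv)
    clamp(rowSums(ru * rv) / sqrt(rowSums(ru^2) * rowSums(rv^2)))
  }
  r1 <- corOf(x[, groups == "case", drop = FALSE])
  r2 <- corOf(x[, groups == "control", drop = FALSE])
  z1 <- atanh(r1); z2 <- atanh(r2)
  Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(Z))
  data.frame(u = edges[, 1L], v = edges[, 2L],
             r_case = unname(r1), r_control = unname(r2),
             z_case = unname(z1), z_control = unname(z2),
             Z = unname(Z), p = unname(p), stringsAsFactors = FALSE)
}

#' Convert differential-correlation p-values to positive edge weights
#'
#' `w = 1 / (-ln max(p, p_floor))`: strongly perturbed edges (small p)
#' become short distances. p-values at 1 (within 1e-12) receive the cap
#' `w_cap` so weights stay finite and strictly positive.
#'
#' @param edge_stats data.frame from [edgeCorrelationTest()]
#' @param p_floor lower clamp on p (default 1e-16)
#' @param w_cap weight assigned when p is 1 (default 1e6)
#' @param graph optional interactome `igraph`; when given, an undirected
#'   weighted copy restricted to the tested edges is returned instead of the
#'   annotated table
#' @return `edge_stats` with a `w` column, or a weighted undirected `igraph`
#' @export
weightEdges <- function(edge_stats, p_floor = 1e-16, w_cap = 1e6,
                        graph = NULL) {
  p <- edge_stats$p
  .stopIf(any(p <= 0 | p > 1), "p-values must lie in (0, 1]")
  w <- 1 / (-log(pmax(p, p_floor)))
  w[p >= 1 - 1e-12] <- w_cap
  edge_stats$w <- w
  if (is.null(graph)) return(edge_stats)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_stats$u, to = edge_stats$v, weight = w),
    directed = FALSE,
    vertices = igraph::V(graph)$name)
  g
}

#' Select seed genes by pathway-level group-perturbation screening
#'
#' For every pathway graph, each measured gene is regressed on its measured
#' pathway parents plus the group indicator; the group coefficient's
#' two-sided p-value measures that gene's perturbation in that pathway
#' context. Each gene keeps its minimum p across the pathways containing it;
#' Benjamini-Hochberg adjustment is applied across genes and seeds are the
#' genes with adjusted p below `alpha`. This is a transparent reading of
#' SEM-based gene-set screening; an externally computed seed list can be
#' used instead anywhere a seed set is accepted.
#'
#' @param pathways named list of directed pathway `igraph`s
#' @param x gene x sample expression matrix (nonparanormal-transformed)
#' @param groups factor/character `case`/`control`
#' @param alpha seed threshold on adjusted p (default 0.05)
#' @return data.frame: `gene`, `p`, `padj`, `seed` (logical), sorted by p
#' @export
selectSeeds <- function(pathways, x, groups, alpha = 0.05) {
  .stopIf(length(pathways) == 0L, "pathway collection is empty")
  groups <- as.character(groups)
  grp <- as.numeric(groups == "case")
  pmin_by_gene <- list()
  any_used <- FALSE
  for (nm in names(pathways)) {
    pg <- pathways[[nm]]
    genes <- intersect(igraph::V(pg)$name, rownames(x))
    if (length(genes) < 1L) { warning(sprintf("pathway %s has no measured genes; skipped", nm)); next }
    any_used <- TRUE
    for (g in genes) {
      parents <- intersect(igraph::V(pg)$name[igraph::neighbors(pg, g, mode = "in")],
                           rownames(x))
      X <- cbind(1, grp)
      if (length(parents))
        X <- cbind(X, t(x[parents, , drop = FALSE]))
      fit <- stats::lm.fit(X, x[g, ])
      res <- fit$residuals
      dfres <- length(res) - ncol(X)
      if (dfres <= 0) next
      s2 <- sum(res^2) / dfres
      XtXinv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(s2 * XtXinv[2L, 2L])
      z <- fit$coefficients[2L] / se
      p <- 2 * stats::pnorm(-abs(z))
      cur <- pmin_by_gene[[g]]
      pmin_by_gene[[g]] <- if (is.null(cur)) p else min(cur, p)
    }
  }
  .stopIf(!any_used, "no pathway overlaps the expression genes")
  genes <- names(pmin_by_gene)
  p <- unlist(pmin_by_gene, use.names = FALSE)
  padj <- .bh(p)
  out <- data.frame(gene = genes, p = p, padj = padj, seed = padj < alpha,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}
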