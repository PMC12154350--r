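treeOf <- function(...) igraph::graph_from_edgelist(rbind(...), directed = FALSE)

test_that("orientation respects reference directions and roots stars outward", {
  tr <- treeOf(c("A", "B"), c("B", "C"))
  ref <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C")),
                                     directed = TRUE)
  oo <- orientAndOrder(tr, ref)
  expect_equal(oo$order, c("A", "B", "C"))
  el <- igraph::as_edgelist(oo$graph)
  expect_setequal(paste(el[, 1], el[, 2]), c("A B", "B C"))
  # star with unknown directions: center first, leaves outward
  star <- treeOf(c("Z", "a"), c("Z", "b"), c("Z", "c"))
  oos <- orientAndOrder(star, reference = NULL)
  expect_equal(oos$order[1], "Z")
  expect_true(all(igraph::as_edgelist(oos$graph)[, 1] == "Z"))
  # oriented random trees are always DAGs (igraph oracle)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    rt <- igraph::sample_tree(n)
    igraph::V(rt)$name <- sprintf("n%02d", sample(n))
    oo <- orientAndOrder(rt, reference = NULL)
    expect_true(igraph::is_dag(oo$graph))
  }
})

test_that("node-wise lasso recovers a planted chain and rejects noise edges", {
  set.seed(12)
  n <- 2000
  x1 <- stats::rnorm(n); x2 <- x1 + stats::rnorm(n); x3 <- x2 + stats::rnorm(n)
  x <- rbind(g1 = x1, g2 = x2, g3 = x3)
  x <- x / apply(x, 1, stats::sd)
  cands <- dagNodewiseLasso(x, c("g1", "g2", "g3"))
  expect_length(cands, 11)   # grid 0.05..0.15 by 0.01
  for (m in cands) {
    keys <- paste(edgeTable(m)$parent, edgeTable(m)$child)
    expect_true(all(c("g1 g2", "g2 g3") %in% keys))
  }
  # independent noise: false-edge rate stays low at the loosest threshold
  fp <- vapply(1:20, function(i) {
    z <- matrix(stats::rnorm(8 * n), 8, n,
                dimnames = list(sprintf("h%d", 1:8), NULL))
    cands <- dagNodewiseLasso(z, rownames(z), beta_grid = 0.15)
    nrow(edgeTable(cands[[1]])) / choose(8, 2)
  }, numeric(1))
  expect_lt(mean(fp), 0.02)
})

test_that("optimal-DAG selection prefers sparsity within the SRMR slack", {
  rm1 <- randomDagModel(p = 3, n = 30)
  denser <- rm1$model
  # duplicate model with an extra spurious zero-coefficient edge row
  sparser <- denser
  denser@edges <- rbind(denser@edges,
                        data.frame(child = "g3", parent = "g1", beta = 0,
                                   se = 1, z = 0, p = 1, padj = 1))
  got <- selectOptimalDag(list(denser, sparser), rm1$x)
  expect_equal(nrow(edgeTable(got)), nrow(sparser@edges))
  single <- selectOptimalDag(list(sparser), rm1$x)
  expect_equal(edgeTable(single), edgeTable(sparser))
})

test_that("group-model OLS is consistent and handles empty edge sets", {
  set.seed(13)
  n <- 1e5
  xp <- stats::rnorm(n); yc <- 0.5 * xp + stats::rnorm(n)
  x <- rbind(X = xp, Y = yc)
  dag <- igraph::graph_from_edgelist(rbind(c("X", "Y")), directed = TRUE)
  fit <- fitGroupModel(dag, x)
  expect_gt(edgeTable(fit)$beta, 0.49); expect_lt(edgeTable(fit)$beta, 0.51)
  # empty edge set: B = 0, Psi = sample variances
  dag0 <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c("X", "Y"))
  f0 <- fitGroupModel(dag0, x)
  expect_true(all(coefMatrix(f0) == 0))
  expect_equal(unname(residualVariances(f0)),
               unname(apply(x, 1, stats::var)), tolerance = 1e-12)
  expect_error(fitGroupModel(dag, x[1, , drop = FALSE]), "missing")
  xz <- x; xz["Y", ] <- 1
  expect_error(fitGroupModel(dag, xz), "zero-variance")
})

test_that("a saturated fit reproduces the sample covariance exactly", {
  set.seed(14)
  p <- 6; n <- 40
  x <- matrix(stats::rnorm(p * n), p, n,
              dimnames = list(sprintf("g%d", 1:p), NULL))
  ord <- rownames(x)
  full <- igraph::graph_from_edgelist(
    do.call(rbind, lapply(2:p, function(i)
      cbind(ord[seq_len(i - 1)], ord[i]))), directed = TRUE)
  fit <- fitGroupModel(full, x)
  I <- diag(p)
  Sigma <- solve(I - coefMatrix(fit)) %*% diag(residualVariances(fit)) %*%
    t(solve(I - coefMatrix(fit)))
  S <- stats::cov(t(x))
  expect_lt(max(abs(Sigma - S)), 1e-8)
  expect_lt(srmr(fit, x)$srmr, 1e-8)
})

test_that("SRMR matches hand values and the path-tracing oracle", {
  # two variables, independence model, observed r constructed to be 0.5
  xv <- c(-3, -1, 1, 3); zv <- c(1, -1, -1, 1)
  xv <- xv / sqrt(sum(xv^2)); zv <- zv / sqrt(sum(zv^2))
  y <- 0.5 * xv + sqrt(0.75) * zv
  x <- rbind(a = xv, b = y)
  ord <- c("a", "b")
  B <- matrix(0, 2, 2, dimnames = list(ord, ord))
  indep <- methods::new("DagModel", order = ord, B = B,
                        Psi = stats::setNames(apply(x, 1, stats::var), ord),
                        edges = data.frame(child = character(0),
                                           parent = character(0),
                                           beta = numeric(0), se = numeric(0),
                                           z = numeric(0), p = numeric(0),
                                           padj = numeric(0)),
                        tau = NA_real_, label = "independence")
  expect_equal(stats::cor(x[1, ], x[2, ]), 0.5, tolerance = 1e-12)
  expect_equal(srmr(indep, x)$srmr, sqrt(0.25 / 3), tolerance = 1e-6)
  # agreement with an independent path-tracing evaluation
  set.seed(15)
  for (i in 1:10) {
    rm <- randomDagModel()
    expect_equal(srmr(rm$model, rm$x)$srmr,
                 pathTracingSRMR(rm$model@B, rm$model@Psi, rm$x),
                 tolerance = 1e-10)
  }
})

test_that("indirect effects sum coefficient products over directed paths", {
  ord <- c("A", "B", "D", "C")
  B <- matrix(0, 4, 4, dimnames = list(ord, ord))
  B["B", "A"] <- 0.5; B["C", "B"] <- 0.4
  B["D", "A"] <- 0.4; B["C", "D"] <- 0.75   # parallel paths 0.2 and 0.3
  m <- methods::new("DagModel", order = ord, B = B,
                    Psi = stats::setNames(rep(1, 4), ord),
                    edges = data.frame(), tau = NA_real_, label = "hand")
  eff <- indirectEffects(m, "A", "C")
  expect_equal(eff$indirect, 0.5 * 0.4 + 0.4 * 0.75)
  expect_equal(eff$direct, 0)
  expect_equal(indirectEffects(m, "C", "A")$total, 0)  # no directed path
  chain <- indirectEffects(m, "A", "B")
  expect_equal(chain$direct, 0.5); expect_equal(chain$indirect, 0)
})

test_that("perturbation model flags planted shifts and edge differences", {
  set.seed(16)
  dag <- genDag(15, 0.2, seed = 50)
  betas <- .trueBetasFor(dag, seed = 50)
  pn <- stats::setNames(1, igraph::V(dag)$name[1])
  pe <- stats::setNames(0.8, names(betas)[1])
  hitsN <- hitsE <- logical(10)
  for (i in 1:10) {
    sim <- genTwoGroupExpression(dag, betas, pn, pe, 150, 150, seed = 200 + i)
    pm <- fitPerturbationModel(dag, sim$expression, sim$groups)
    ne <- nodeEffects(pm)
    hitsN[i] <- ne$padj[ne$gene == names(pn)] < 0.05 &&
      ne$direction[ne$gene == names(pn)] == "up"
    ed <- edgeDiffs(pm)
    key <- paste(ed$parent, ed$child, sep = "|")
    hitsE[i] <- ed$padj[key == names(pe)] < 0.05
  }
  expect_gte(sum(hitsN), 9)
  expect_gte(sum(hitsE), 9)
})

test_that("group coefficients equal intercept differences for parent-free nodes", {
  set.seed(17)
  dag <- genDag(6, 0.3, seed = 60)
  betas <- .trueBetasFor(dag, seed = 60)
  sim <- genTwoGroupExpression(dag, betas, n_case = 80, n_control = 80, seed = 61)
  pm <- fitPerturbationModel(dag, sim$expression, sim$groups)
  roots <- names(Filter(function(d) d == 0,
                        igraph::degree(dag, mode = "in")))
  for (r in roots) {
    est <- nodeEffects(pm)$estimate[nodeEffects(pm)$gene == r]
    d <- mean(sim$expression[r, sim$groups == "case"]) -
         mean(sim$expression[r, sim$groups == "control"])
    expect_equal(est, d, tolerance = 1e-10)
  }
})

test_that("perturbation calls are calibrated when groups are exchangeable", {
  set.seed(18)
  dag <- genDag(12, 0.2, seed = 70)
  betas <- .trueBetasFor(dag, seed = 70)
  fr <- vapply(1:50, function(i) {
    sim <- genTwoGroupExpression(dag, betas, n_case = 60, n_control = 60,
                                 seed = 300 + i)
    pm <- fitPerturbationModel(dag, sim$expression, sim$groups)
    mean(nodeEffects(pm)$padj < 0.05)
  }, numeric(1))
  expect_lte(mean(fr), 0.07)
})

test_that("active-module extraction uses strict thresholds on adjusted p", {
  ne <- data.frame(gene = c("a", "b", "c"), estimate = c(1, -1, 2),
                   se = 1, z = 1, p = c(0.001, 0.04, 0.05),
                   padj = c(0.001, 0.04, 0.05),
                   direction = c("up", "down", "up"))
  ed <- data.frame(child = "b", parent = "a", beta_case = 1, beta_control = 0,
                   estimate = 1, se = 1, z = 1, p = 0.01, padj = 0.01)
  dm <- randomDagModel(3)$model
  pm <- methods::new("PerturbationModel", nodeEffects = ne, edgeDiffs = ed,
                     caseModel = dm, controlModel = dm)
  mod <- extractActiveModule(pm, alpha = 0.05)
  expect_setequal(mod@nodes$gene, c("a", "b"))     # padj == 0.05 excluded
  expect_equal(nrow(mod@edges), 1)
  ne1 <- ne; ne1$padj <- 1
  ed1 <- ed; ed1$padj <- 1
  pm1 <- methods::new("PerturbationModel", nodeEffects = ne1, edgeDiffs = ed1,
                      caseModel = dm, controlModel = dm)
  mod1 <- extractActiveModule(pm1, alpha = 0.05)
  expect_equal(nrow(mod1@nodes), 0); expect_equal(nrow(mod1@edges), 0)
})
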