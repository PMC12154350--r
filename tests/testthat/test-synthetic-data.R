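test_that("random DAGs are acyclic with the expected edge counts", {
  expect_equal(igraph::ecount(genDag(1, 0.5, seed = 1)), 0)
  expect_equal(igraph::ecount(genDag(8, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(genDag(4, 1, seed = 1)), 6)  # n(n-1)/2
  for (s in 1:15) {
    g <- genDag(12, 0.4, seed = s)
    expect_true(igraph::is_dag(g))
  }
  # deterministic given seed
  g1 <- genDag(10, 0.3, seed = 42); g2 <- genDag(10, 0.3, seed = 42)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("SEM generator plants edge coefficients and node shifts exactly", {
  # empty DAG, no perturbations: iid standard normals
  g0 <- genDag(4, 0, seed = 1)
  sim0 <- genTwoGroupExpression(g0, numeric(0), n_case = 2000,
                                n_control = 2000, seed = 1)
  expect_lt(abs(mean(sim0$expression)), 0.05)
  expect_lt(abs(stats::var(as.vector(sim0$expression)) - 1), 0.05)

  # single edge X -> Y with beta 0.5: OLS slope recovers it
  g1 <- igraph::graph_from_edgelist(rbind(c("X", "Y")), directed = TRUE)
  sim1 <- genTwoGroupExpression(g1, c("X|Y" = 0.5), n_case = 50000,
                                n_control = 50000, seed = 2)
  slope <- stats::coef(stats::lm(sim1$expression["Y", ] ~ sim1$expression["X", ]))[2]
  expect_lt(abs(slope - 0.5), 0.02)

  # delta = 1 on a node: case-minus-control mean near 1
  sim2 <- genTwoGroupExpression(g0, numeric(0),
                                perturbed_nodes = c(N002 = 1),
                                n_case = 10000, n_control = 10000, seed = 3)
  d <- mean(sim2$expression["N002", sim2$groups == "case"]) -
       mean(sim2$expression["N002", sim2$groups == "control"])
  expect_lt(abs(d - 1), 0.05)

  # perturbed edge must be a DAG edge
  expect_error(genTwoGroupExpression(g1, c("X|Y" = 0.5),
                                     perturbed_edges = c("Y|X" = 1),
                                     n_case = 10, n_control = 10),
               "perturbed edge")
})

test_that("counts follow the NB mean-variance law and are reproducible", {
  lat <- matrix(log(50), 1, 1e5, dimnames = list("g", sprintf("s%d", 1:1e5)))
  pois <- genCounts(lat, rep(1, 1e5), nb_dispersion = 0, seed = 5)
  expect_lt(abs(stats::var(as.numeric(pois)) / mean(pois) - 1), 0.1)

  lat2 <- matrix(log(100), 1, 1e5, dimnames = dimnames(lat))
  nb <- genCounts(lat2, rep(1, 1e5), nb_dispersion = 2, seed = 6)
  expect_lt(abs(stats::var(as.numeric(nb)) / (100 + 2 * 100^2) - 1), 0.1)

  expect_identical(genCounts(lat2[, 1:100, drop = FALSE], rep(1, 100), 0.5, seed = 9),
                   genCounts(lat2[, 1:100, drop = FALSE], rep(1, 100), 0.5, seed = 9))
  expect_error(genCounts(matrix(Inf, 1, 1), 1, 0, 1), "finite")
})

test_that("survival generator is null-calibrated and recovers a planted HR", {
  x0 <- matrix(stats::rnorm(2000), 1, 2000,
               dimnames = list("g", sprintf("s%d", 1:2000)))
  # null: zero hazard coefficient
  sv0 <- genSurvival(x0, c(g = 0), censor_max = 15, seed = 11)
  cx0 <- coxFit(sv0, x0["g", ])
  expect_lt(abs(cx0$beta), 0.1)
  # binary expression with beta = log 2: fitted HR near 2
  # (averaged over replicates to tame Monte-Carlo noise at n = 2000)
  xb <- matrix(rep(0:1, 1000), 1, 2000,
               dimnames = list("g", sprintf("s%d", 1:2000)))
  hrs <- vapply(1:3, function(k) {
    svb <- genSurvival(xb, c(g = log(2)), censor_max = 30, seed = 11 + k)
    coxFit(svb, xb["g", ])$hr
  }, numeric(1))
  expect_gt(mean(hrs), 1.8); expect_lt(mean(hrs), 2.2)
  # vanishing censoring window censors everyone
  svc <- genSurvival(xb, c(g = log(2)), censor_max = 1e-9, seed = 13)
  expect_true(all(svc$event == 0))
  expect_error(genSurvival(xb, c(g = 1), censor_max = 0), "censor_max")
})

test_that("panel selection is deterministic with floor(fraction * n) genes", {
  genes <- sprintf("G%05d", seq_len(56609))
  expect_identical(genPanel(genes, 0, seed = 1), character(0))
  expect_setequal(genPanel(genes[1:50], 1, seed = 1), genes[1:50])
  expect_length(genPanel(genes, 720 / 56609, seed = 1), 720)
  expect_identical(genPanel(genes, 0.1, seed = 3), genPanel(genes, 0.1, seed = 3))
})

test_that("ground truth survives serialization and reruns are identical", {
  cfg <- simConfig(seed = 21, n_case = 12, n_control = 12, n_genes = 120,
                   dag_nodes = 20, library_size_range = c(1e6, 2e6))
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(SummarizedExperiment::assay(s1$se),
                   SummarizedExperiment::assay(s2$se))
  dir <- withr::local_tempdir()
  paths <- writeStudy(s1, dir)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(names(truth$perturbed_nodes)),
               sort(names(s1$truth$perturbed_nodes)))
  expect_equal(unlist(truth$size_factors[colnames(s1$se)]),
               s1$truth$size_factors[colnames(s1$se)], tolerance = 1e-12)
  expect_equal(truth$dag_edges$beta, s1$truth$dag_edges$beta, tolerance = 1e-12)
})

test_that("per-operation substreams keep generators independent", {
  lat <- matrix(log(30), 2, 6, dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  c1 <- genCounts(lat, rep(1, 6), 0.1, seed = 77)
  invisible(genDag(30, 0.5, seed = 77))   # interleaved call must not matter
  c2 <- genCounts(lat, rep(1, 6), 0.1, seed = 77)
  expect_identical(c1, c2)
})
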