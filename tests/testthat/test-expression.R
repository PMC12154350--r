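mkSE <- function(counts, group = NULL, ...) {
  if (is.null(group)) group <- rep("case", ncol(counts))
  meta <- data.frame(group = group, ...)
  countsExperiment(counts, meta)
}

test_that("sample QC drops low-coverage samples by declared or summed reads", {
  m <- matrix(c(10, 30e6, 40e6), nrow = 1,
              dimnames = list("g1", c("s1", "s2", "s3")))
  se <- mkSE(m)
  expect_equal(ncol(suppressMessages(qcFilterSamples(se, 0))), 3)
  kept <- suppressMessages(qcFilterSamples(se, 25e6))
  expect_equal(colnames(kept), c("s2", "s3"))
  # declared library_size wins over column sums
  se2 <- mkSE(m, library_size = c(26e6, 10, 30e6))
  kept2 <- suppressMessages(qcFilterSamples(se2, 25e6))
  expect_equal(colnames(kept2), c("s1", "s3"))
  expect_error(suppressMessages(qcFilterSamples(se, 1e12)), "every sample")
})

test_that("gene filter uses a strict count threshold and is idempotent", {
  n <- 12
  m <- rbind(exactly10 = rep(10L, n),
             eleven10x = c(rep(11L, 10), rep(0L, n - 10)),
             low = rep(1L, n))
  colnames(m) <- sprintf("s%d", 1:n)
  se <- mkSE(m)
  f <- suppressMessages(filterGenes(se, 10, 10))
  expect_equal(rownames(f), "eleven10x")   # strict ">", boundary kept
  expect_equal(nrow(suppressMessages(filterGenes(se, 10, 0))), 3)
  f2 <- suppressMessages(filterGenes(f, 10, 10))
  expect_identical(SummarizedExperiment::assay(f),
                   SummarizedExperiment::assay(f2))
})

test_that("median-of-ratios size factors match hand values and DESeq2", {
  m <- matrix(rep(c(5L, 9L, 13L), 2), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(sizeFactorsMedianOfRatios(m)), c(1, 1))
  # column 2 = 2 x column 1: factors 1/sqrt(2), sqrt(2)
  m2 <- cbind(s1 = c(5L, 9L, 13L), s2 = c(10L, 18L, 26L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(sizeFactorsMedianOfRatios(m2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # an all-zero gene is excluded from the reference, result unchanged
  m3 <- rbind(m2, zero = c(0L, 0L))
  expect_equal(sizeFactorsMedianOfRatios(m3), sizeFactorsMedianOfRatios(m2))
  expect_error(sizeFactorsMedianOfRatios(rbind(zero = c(0L, 0L))), "positive")
  # independent implementation agreement on a larger random matrix
  set.seed(1)
  big <- matrix(rnbinom(200 * 10, mu = 60, size = 5), 200, 10,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:10)))
  expect_equal(unname(sizeFactorsMedianOfRatios(big)),
               unname(DESeq2::estimateSizeFactorsForMatrix(big)),
               tolerance = 1e-10)
})

test_that("size factors recover planted factors up to a constant", {
  # gene baselines + NB noise isolate the estimator from group effects
  set.seed(31)
  n <- 60
  base <- stats::runif(2000, log(20), log(2000))
  lat <- matrix(base, 2000, n,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:n)))
  sf_true <- exp(stats::rnorm(n, 0, 0.2))
  sf_true <- sf_true / exp(mean(log(sf_true)))
  counts <- genCounts(lat, sf_true, nb_dispersion = 0.05, seed = 31)
  sf <- sizeFactorsMedianOfRatios(counts)
  ratio <- sf / sf_true
  ratio <- ratio / exp(mean(log(ratio)))   # remove the common constant
  expect_lt(max(abs(ratio - 1)), 0.05)
})

test_that("log normalization has the stated closed form and invariances", {
  m <- matrix(c(0L, 7L), 1, 2, dimnames = list("g", c("s1", "s2")))
  v <- normalizeLog(m, c(s1 = 1, s2 = 1), pseudocount = 1)
  expect_equal(unname(v[1, ]), c(0, 3))                   # log2(8) = 3
  expect_equal(unname(normalizeLog(matrix(0L, 1, 1), 1, 0.25)[1, 1]), -2)
  expect_equal(normalizeLog(matrix(14L, 1, 1), 2, 1),
               normalizeLog(matrix(7L, 1, 1), 1, 1), ignore_attr = TRUE)
})

test_that("PCA attributes variance to the dominant axes and covariates", {
  n <- 20
  m <- rbind(varying = c(rep(0, n / 2), rep(4, n / 2)) + stats::rnorm(n, 0, 1e-3),
             flat1 = rep(1, n), flat2 = rep(2, n))
  colnames(m) <- sprintf("s%d", 1:n)
  ps <- pcaTopVariable(m, k = 3)
  expect_gt(ps$var_frac[["PC1"]], 0.999)
  # two perfectly correlated genes: one informative axis
  m2 <- rbind(a = stats::rnorm(n), b = 0)
  m2["b", ] <- 2 * m2["a", ]
  colnames(m2) <- sprintf("s%d", 1:n)
  ps2 <- pcaTopVariable(m2, k = 2)
  expect_lt(ps2$var_frac[["PC2"]], 1e-12)
  expect_true(all(diff(ps$var_frac) <= 1e-12))
  # a planted group split loads onto PC1's covariate R^2
  grp <- rep(c("case", "control"), each = n / 2)
  ps3 <- pcaTopVariable(m, k = 3, metadata = data.frame(group = grp))
  expect_gt(ps3$r2["PC1", "group"], 0.99)
  expect_error(pcaTopVariable(m[, 1, drop = FALSE], k = 2), "2 samples")
})

test_that("differential expression applies both significance gates", {
  set.seed(2)
  n <- 50
  grp <- rep(c("case", "control"), each = n)
  base <- matrix(stats::rnorm(3 * 2 * n, sd = 0.1), 3, 2 * n,
                 dimnames = list(c("flat", "small", "big"),
                                 sprintf("s%d", 1:(2 * n))))
  base["small", grp == "case"] <- base["small", grp == "case"] + 0.8
  base["big", grp == "case"] <- base["big", grp == "case"] + 2
  de <- differentialExpression(base, grp)
  de <- de[match(c("flat", "small", "big"), de$gene), ]
  expect_equal(de$status, c("ns", "ns", "up"))   # small fails the lfc gate
  expect_lt(de$padj[2], 0.01)                    # ... despite tiny padj
  expect_equal(de$log2fc[1], mean(base["flat", grp == "case"]) -
                 mean(base["flat", grp == "control"]))
  # identical values in both groups: lfc 0, p 1, ns
  cst <- matrix(5, 1, 2 * n, dimnames = list("c", sprintf("s%d", 1:(2 * n))))
  dc <- differentialExpression(cst, grp)
  expect_equal(dc$log2fc, 0); expect_equal(dc$p, 1); expect_equal(dc$status, "ns")
  expect_error(differentialExpression(base[, 1:3], grp[1:3]), "2 samples")
})

test_that("planted two-unit fold changes are called up essentially always", {
  set.seed(3)
  hits <- vapply(1:30, function(i) {
    n <- 50
    grp <- rep(c("case", "control"), each = n)
    m <- matrix(stats::rnorm(40 * 2 * n, sd = 0.3), 40, 2 * n,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:(2 * n))))
    m["g01", grp == "case"] <- m["g01", grp == "case"] + 2
    de <- differentialExpression(m, grp)
    de$status[de$gene == "g01"] == "up"
  }, logical(1))
  expect_true(all(hits))
})

test_that("BH keeps the false discovery rate controlled on null genes", {
  set.seed(4)
  fdr <- vapply(1:200, function(i) {
    m <- matrix(stats::rnorm(200 * 20), 200, 20,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:20)))
    grp <- rep(c("case", "control"), each = 10)
    de <- differentialExpression(m, grp)
    R <- sum(de$padj < 0.05)
    if (R == 0) 0 else R / R   # all discoveries on null data are false
  }, numeric(1))
  expect_lte(mean(fdr), 0.07)
})

test_that("panel intersection keeps significant panel genes with annotation", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(2, -2, 2, 2), p = 0, padj = c(0, 0, 0, 1),
                   status = c("up", "down", "up", "ns"))
  expect_equal(nrow(intersectPanel(de, c("x", "y"))), 0)
  got <- intersectPanel(de, c("b", "c", "d"))
  expect_equal(got$gene, c("b", "c"))
  expect_equal(got$status, c("down", "up"))
})

test_that("a synthetic run recovers exactly the planted panel DEGs", {
  set.seed(5)
  n <- 60
  grp <- rep(c("case", "control"), each = n)
  genes <- sprintf("g%03d", 1:200)
  m <- matrix(stats::rnorm(200 * 2 * n, sd = 0.3), 200, 2 * n,
              dimnames = list(genes, sprintf("s%d", 1:(2 * n))))
  planted <- genes[1:20]
  m[planted, grp == "case"] <- m[planted, grp == "case"] + 2
  panel <- c(planted, genes[101:130])
  de <- differentialExpression(m, grp)
  expect_setequal(intersectPanel(de, panel)$gene, planted)
})
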