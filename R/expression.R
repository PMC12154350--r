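#' Assemble a counts experiment
#'
#' Wraps a raw gene x sample count matrix and its sample metadata into a
#' `SummarizedExperiment`, validating the invariants the pipeline relies on:
#' integral non-negative counts, unique gene and sample ids, and a group
#' label for every sample.
#'
#' @param counts gene x sample matrix of non-negative integers
#' @param meta data.frame (or DataFrame) with one row per sample; must
#'   contain a `group` column; a `library_size` column, when present, is the
#'   declared sequencing depth used by read-count QC
#' @return a `SummarizedExperiment` with a `counts` assay
#' @export
countsExperiment <- function(counts, meta) {
  counts <- as.matrix(counts)
  .stopIf(any(counts < 0), "counts must be non-negative")
  .stopIf(any(counts != round(counts)), "counts must be integers")
  .stopIf(anyDuplicated(rownames(counts)) > 0, "duplicate gene ids")
  .stopIf(anyDuplicated(colnames(counts)) > 0, "duplicate sample ids")
  meta <- S4Vectors::DataFrame(meta)
  .stopIf(nrow(meta) != ncol(counts), "one metadata row per sample required")
  .stopIf(!"group" %in% colnames(meta), "metadata must contain a group column")
  .stopIf(any(is.na(meta$group)), "every sample needs a group label")
  rownames(meta) <- colnames(counts)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(as.integer(counts), nrow = nrow(counts),
                                  dimnames = dimnames(counts))),
    colData = meta)
}

#' Drop low-coverage samples
#'
#' Removes samples whose sequencing depth falls below `min_reads`
#' (default 25 million). Depth is the declared `library_size` metadata
#' column when present, otherwise the column sum of assigned counts.
#'
#' @param se counts `SummarizedExperiment`
#' @param min_reads minimum reads to retain a sample
#' @return the filtered experiment; a message reports samples in/out
#' @export
qcFilterSamples <- function(se, min_reads = 25e6) {
  .stopIf(min_reads < 0, "min_reads must be >= 0")
  cd <- SummarizedExperiment::colData(se)
  depth <- if ("library_size" %in% colnames(cd)) as.numeric(cd$library_size)
           else colSums(SummarizedExperiment::assay(se, "counts"))
  keep <- depth >= min_reads
  .stopIf(!any(keep), "QC removed every sample (min_reads = %g)", min_reads)
  message(sprintf("qcFilterSamples: kept %d / %d samples (min_reads = %g)",
                  sum(keep), length(keep), min_reads))
  se[, keep]
}

#' Drop weakly expressed genes
#'
#' Keeps gene g when strictly more than `min_count` counts are observed in
#' at least `min_samples` samples (the default reproduces the usual
#' ">10 counts in at least 10 samples" rule; the count inequality is strict).
#'
#' @param se counts `SummarizedExperiment`
#' @param min_count strict per-sample count threshold
#' @param min_samples number of samples that must exceed it
#' @return the filtered experiment
#' @export
filterGenes <- function(se, min_count = 10, min_samples = 10) {
  .stopIf(min_count < 0 || min_samples < 0, "thresholds must be >= 0")
  counts <- SummarizedExperiment::assay(se, "counts")
  keep <- rowSums(counts > min_count) >= min_samples
  if (!any(keep)) warning("gene filter removed every gene")
  message(sprintf("filterGenes: kept %d / %d genes (> %d counts in >= %d samples)",
                  sum(keep), length(keep), min_count, min_samples))
  se[keep, ]
}

#' Median-of-ratios size factors
#'
#' The reference expression of each gene is its geometric mean across
#' samples, computed over genes with all-positive counts; the size factor of
#' sample j is the median over those genes of `count[g, j] / reference[g]`.
#'
#' @param counts gene x sample count matrix or `SummarizedExperiment`
#' @return named positive numeric vector of per-sample size factors
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  pos <- rowSums(counts <= 0) == 0L
  .stopIf(!any(pos), "no gene has positive counts in every sample")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)                       # log geometric mean
  sf <- apply(lc - ref, 2L, function(r) exp(stats::median(r)))
  stats::setNames(sf, colnames(counts))
}

#' Log2-normalize counts
#'
#' `log2(count / size_factor + pseudocount)`, monotone in the count for a
#' fixed sample.
#'
#' @param counts gene x sample matrix or `SummarizedExperiment`
#' @param size_factors positive per-sample factors (default: median-of-ratios
#'   on `counts`)
#' @param pseudocount added before the log (default 1)
#' @return numeric matrix of normalized log2 expression
#' @export
normalizeLog <- function(counts, size_factors = NULL, pseudocount = 1) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  if (is.null(size_factors)) size_factors <- sizeFactorsMedianOfRatios(counts)
  .stopIf(any(size_factors <= 0), "size factors must be positive")
  log2(sweep(counts, 2L, size_factors, `/`) + pseudocount)
}

#' PCA variance attribution on the most variable genes
#'
#' Selects the `k` most variable genes (default 500), centers them, runs a
#' principal component analysis over samples, and reports each component's
#' variance fraction together with the R-squared of the component scores
#' regressed on each metadata covariate — the usual check of how much
#' transcriptomic variability disease status, sex and grade explain.
#'
#' @param normalized gene x sample matrix of normalized expression
#' @param k number of top-variance genes (default 500)
#' @param metadata data.frame of per-sample covariates to associate with the
#'   component scores
#' @param n_components number of components to report (default 10)
#' @return list with `var_frac` (named numeric) and `r2` (component x
#'   covariate matrix)
#' @export
pcaTopVariable <- function(normalized, k = 500, metadata = NULL,
                           n_components = 10) {
  .stopIf(k < 1, "k must be >= 1")
  .stopIf(ncol(normalized) < 2, "PCA needs at least 2 samples")
  v <- apply(normalized, 1L, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(k, nrow(normalized)))]
  x <- t(normalized[top, , drop = FALSE])   # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  m <- min(n_components, length(var_frac))
  var_frac <- stats::setNames(var_frac[seq_len(m)], paste0("PC", seq_len(m)))
  r2 <- NULL
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    r2 <- sapply(metadata, function(cov) {
      vapply(seq_len(m), function(i) {
        if (length(unique(cov)) < 2) return(NA_real_)
        summary(stats::lm(pc$x[, i] ~ cov))$r.squared
      }, numeric(1))
    })
    rownames(r2) <- names(var_frac)
  }
  list(var_frac = var_frac, r2 = r2)
}

#' Two-group differential expression on the normalized log scale
#'
#' Per-gene Welch t test of case versus control on log2-normalized values
#' with Benjamini-Hochberg adjustment. This is a deliberately simple
#' stand-in for a negative-binomial GLM: its interface (gene, log2fc, p,
#' padj, status) is the contract, so an externally computed DE table with
#' the same columns can be substituted anywhere downstream. The log2 fold
#' change is the difference of group means of the log2-normalized values.
#' Genes with zero variance in both groups are assigned p = 1 (or p = 0 if
#' their constant means differ), never dropped.
#'
#' @param normalized gene x sample matrix of log2-normalized expression
#' @param groups factor/character with levels `case`, `control`
#' @param padj_cut,lfc_cut significance gates for the status call
#'   (`up`: padj < padj_cut and log2fc >= lfc_cut; `down`: padj < padj_cut
#'   and log2fc <= -lfc_cut; else `ns`)
#' @return data.frame: `gene`, `log2fc`, `p`, `padj`, `status`
#' @export
differentialExpression <- function(normalized, groups, padj_cut = 0.01,
                                   lfc_cut = 1) {
  groups <- as.character(groups)
  .stopIf(!all(groups %in% c("case", "control")),
          "groups must be 'case'/'control'")
  i1 <- groups == "case"; i2 <- groups == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  .stopIf(n1 < 2 || n2 < 2, "each group needs at least 2 samples")
  x1 <- normalized[, i1, drop = FALSE]; x2 <- normalized[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
  padj <- .bh(p)
  status <- rep("ns", length(p))
  status[padj < padj_cut & lfc >= lfc_cut] <- "up"
  status[padj < padj_cut & lfc <= -lfc_cut] <- "down"
  data.frame(gene = rownames(normalized), log2fc = unname(lfc),
             p = unname(p), padj = unname(padj), status = status,
             stringsAsFactors = FALSE)
}

#' Intersect significant genes with a gene panel
#'
#' Returns the panel members among the significant (non-`ns`) DE genes,
#' with their up/down annotation preserved.
#'
#' @param de_records data.frame from [differentialExpression()]
#' @param panel character vector of panel gene symbols
#' @return data.frame subset of `de_records`
#' @export
intersectPanel <- function(de_records, panel) {
  hit <- de_records$status != "ns" & de_records$gene %in% panel
  out <- de_records[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
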