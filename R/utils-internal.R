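# Internal helpers shared across modules.

# Per-operation random substream: a deterministic 32-bit seed derived from the
# master seed and an operation tag, so that adding one generator call to a
# workflow does not shift the streams of the others.
.substream <- function(seed, tag) {
  v <- utf8ToInt(tag)
  off <- sum(v * seq_along(v)) %% 1000003L
  as.integer((abs(as.numeric(seed)) %% 2147000000 + off * 131) %% 2147483647)
}

# round half away from zero (base round() is round-half-even)
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# tiny FNV-1a-style string hash, for run manifests
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2147483647), ch)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)

# edge key helpers: edges identified as "u|v" (directed) or sorted (undirected)
.edgeKey <- function(u, v) paste(u, v, sep = "|")
.undirKey <- function(u, v) ifelse(u < v, paste(u, v, sep = "|"), paste(v, u, sep = "|"))

# Benjamini-Hochberg, via stats
.bh <- function(p) stats::p.adjust(p, method = "BH")

# deterministic TSV writer (fixed 15-digit representation keeps reruns
# byte-identical across platforms)
.writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.15g", df[[j]])
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(e) paste(e, collapse = ","), character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
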