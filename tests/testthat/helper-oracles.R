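# Independent oracles and fixture builders used across test files.
# The oracles deliberately take different computational routes than the
# package implementations they check.

# Direct double-sum evaluation of conditional entropy from a joint count
# matrix (rows = contexts, cols = targets): H = -sum_i P(a_i) sum_j
# P(b_j|a_i) log2 P(b_j|a_i).
oracleConditionalEntropy <- function(jointCounts) {
  n <- sum(jointCounts)
  H <- 0
  for (i in seq_len(nrow(jointCounts))) {
    rowTot <- sum(jointCounts[i, ])
    if (rowTot == 0) next
    pa <- rowTot / n
    for (j in seq_len(ncol(jointCounts))) {
      pba <- jointCounts[i, j] / rowTot
      if (pba > 0) H <- H - pa * pba * log2(pba)
    }
  }
  H
}

# Pearson r via the covariance/variance route (stats::cov / stats::var),
# independent of the centred cross-product sums in pearsonCor().
oraclePearson <- function(x, y) {
  stats::cov(x, y) / sqrt(stats::var(x) * stats::var(y))
}

# A random joint count matrix and the matching context/target data frame
# that estimateTP() accepts (order 0 keys all targets to the empty context;
# here we emulate order >= 2 contexts with one-offset patterns).
randomJoint <- function(nCtx, nTgt, maxCount = 6L) {
  counts <- matrix(sample(0:maxCount, nCtx * nTgt, replace = TRUE),
                   nrow = nCtx)
  if (sum(counts) == 0) counts[1, 1] <- 1L
  counts
}

jointToPairs <- function(counts) {
  ctxKeys <- paste0("(", seq_len(nrow(counts)), ")")
  rows <- which(counts > 0, arr.ind = TRUE)
  data.frame(
    context = rep(ctxKeys[rows[, 1]], counts[counts > 0]),
    target = rep(as.integer(rows[, 2]), counts[counts > 0]),
    stringsAsFactors = FALSE)
}

# Vectors with an exactly prescribed sample Pearson correlation, built from
# an orthonormalised pair.
vectorsWithExactR <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  x <- x - mean(x)
  z <- stats::residuals(stats::lm(z ~ x))
  xh <- x / sqrt(sum(x^2))
  zh <- z / sqrt(sum(z^2))
  list(x = xh, y = r * xh + sqrt(1 - r^2) * zh)
}

# Empirical chain-convention order-1 transition matrix of a pitch line over
# a fixed interval alphabet.
empiricalChainMatrix <- function(pitches, alphabet) {
  tp <- lineTP(pitches, 1L, "chain")
  tr <- transitions(tp)
  M <- matrix(0, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  ctxVal <- as.integer(gsub("[()]", "", tr$context))
  for (k in seq_len(nrow(tr)))
    M[match(ctxVal[k], alphabet), match(tr$target[k], alphabet)] <- tr$prob[k]
  M
}

# Per-unit melody and bass entropies of a corpus at the generator's own
# order under the chain convention (the quantity the uncertainty knob
# controls), as an n x 2 matrix.
unitEntropies <- function(corpus, ord = 1L) {
  mel <- vapply(linesFor(corpus, voice = "melody"),
                function(l) conditionalEntropy(lineTP(l, ord, "chain")),
                numeric(1))
  bas <- vapply(linesFor(corpus, voice = "bass"),
                function(l) conditionalEntropy(lineTP(l, ord, "chain")),
                numeric(1))
  cbind(melody = mel, bass = bas)
}

# Literal MusicXML writer for parser edge-case tests.
writeRawXML <- function(lines) {
  f <- tempfile(fileext = ".xml")
  writeLines(lines, f)
  f
}

musicxmlHeader <- function(root = "score-partwise") {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<%s version=\"3.1\">", root),
    "  <part-list>",
    "    <score-part id=\"P1\"><part-name>A</part-name></score-part>",
    "    <score-part id=\"P2\"><part-name>B</part-name></score-part>",
    "  </part-list>")
}
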