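# Context bookkeeping for an order-k interval chain over alphabet A:
# contexts are k-tuples of alphabet indices, encoded as a single index with
# the oldest interval most significant. Emitting target j shifts the tuple.
.nextContextIndex <- function(nCtx, nA, order) {
  if (order <= 1L)
    return(matrix(rep(seq_len(nA), each = nCtx), nrow = nCtx))
  base <- nA^(order - 1L)
  outer((seq_len(nCtx) - 1L) %% base, seq_len(nA),
        function(i, j) i * nA + j)
}

.stationaryContext <- function(P, order, tol = 1e-13, maxIter = 10000L) {
  nCtx <- nrow(P); nA <- ncol(P)
  if (order == 1L) {
    pi0 <- rep(1 / nCtx, nCtx)
    for (i in seq_len(maxIter)) {
      pi1 <- as.vector(pi0 %*% P)
      if (max(abs(pi1 - pi0)) < tol)
        return(list(pi = pi1, converged = TRUE))
      pi0 <- pi1
    }
    return(list(pi = pi0, converged = FALSE))
  }
  nxt <- as.vector(.nextContextIndex(nCtx, nA, order))
  pi0 <- rep(1 / nCtx, nCtx)
  for (i in seq_len(maxIter)) {
    w <- as.vector(P * pi0) # column-major: (ctx, target) pairs
    agg <- rowsum(w, nxt)
    pi1 <- numeric(nCtx)
    pi1[as.integer(rownames(agg))] <- agg
    if (max(abs(pi1 - pi0)) < tol)
      return(list(pi = pi1, converged = TRUE))
    pi0 <- pi1
  }
  list(pi = pi0, converged = FALSE)
}

#' Analytic conditional entropy of an interval Markov source
#'
#' Evaluates `H = -sum_a P(a) sum_b P(b|a) log2 P(b|a)` on a true transition
#' matrix, with the context distribution `P(a)` taken as the stationary
#' distribution of the context chain. If the stationary distribution cannot
#' be reached (reducible chain), uniform context weights are used and a
#' warning is raised.
#'
#' @param P row-stochastic matrix (contexts x targets) for order >= 1, or a
#'   probability vector for order 0.
#' @param order the order of the source (0..5); for order k the matrix must
#'   have `ncol(P)^k` rows.
#' @return Entropy in bits.
#' @export
#' @examples
#' analyticEntropy(matrix(0.25, 4, 4), order = 1)  # 2 bits
#' analyticEntropy(diag(4)[, c(2, 3, 4, 1)], order = 1)  # 0 bits
analyticEntropy <- function(P, order = 1L) {
  order <- as.integer(order)
  if (order == 0L) {
    p <- as.vector(P)
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      .stopf("order-0 source must be a probability vector")
    p <- p[p > 0]
    return(-sum(p * log2(p)))
  }
  P <- as.matrix(P)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    .stopf("rows of the transition matrix must be non-negative and sum to 1")
  if (nrow(P) != ncol(P)^order)
    .stopf("an order-%d source over %d intervals needs %d context rows, got %d",
           order, ncol(P), ncol(P)^order, nrow(P))
  st <- .stationaryContext(P, order)
  if (!st$converged) {
    .warnf("context chain did not reach a stationary distribution; using uniform context weights")
    st$pi <- rep(1 / nrow(P), nrow(P))
  }
  rowH <- apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(st$pi * rowH)
}

#' Sample an interval sequence from a Markov source
#'
#' Draws `n` elementary intervals from an order-k chain over an interval
#' alphabet, starting from a context drawn from the stationary distribution.
#' Uses the current RNG state (seed it with `set.seed()` for
#' reproducibility).
#'
#' @param P row-stochastic matrix (contexts x targets), or a probability
#'   vector for order 0.
#' @param n number of intervals to draw.
#' @param alphabet integer vector of interval values, one per column of `P`.
#' @param order order of the source.
#' @return Integer vector of `n` intervals.
#' @export
sampleIntervalChain <- function(P, n, alphabet, order = 1L) {
  order <- as.integer(order)
  n <- as.integer(n)
  if (order == 0L)
    return(sample(as.integer(alphabet), n, replace = TRUE,
                  prob = as.vector(P)))
  P <- as.matrix(P)
  nCtx <- nrow(P); nA <- ncol(P)
  stopifnot(length(alphabet) == nA, nCtx == nA^order)
  st <- .stationaryContext(P, order)
  ctx <- sample.int(nCtx, 1L, prob = pmax(st$pi, 0))
  cum <- lapply(seq_len(nCtx), function(i) cumsum(P[i, ]))
  nxt <- .nextContextIndex(nCtx, nA, order)
  u <- stats::runif(n)
  out <- integer(n)
  for (t in seq_len(n)) {
    j <- findInterval(u[t], cum[[ctx]]) + 1L
    if (j > nA) j <- nA
    out[t] <- j
    ctx <- nxt[ctx, j]
  }
  as.integer(alphabet)[out]
}

.tonics <- c("C", "Db", "D", "Eb", "E", "F", "Gb", "G", "Ab", "A", "Bb", "B")

#' Generate a synthetic two-voice corpus with known ground truth
#'
#' Builds a corpus of paired melody/bass voice lines sampled from order-k
#' interval Markov sources with a controlled structure that emulates what
#' the corpus analysis assumes about real music:
#' \itemize{
#'   \item one base transition matrix per corpus (rows Dirichlet with
#'     concentration `baseConcentration`) shared by every piece and voice —
#'     the "common practice" component;
#'   \item voice-level and unit-level Dirichlet perturbations mixed in with
#'     weight `voicePerturbation`, giving each voice a systematic profile
#'     and each piece an idiosyncratic one;
#'   \item a per-unit "uncertainty" temperature that sharpens (T < 1) or
#'     flattens (T > 1) every row of that unit's matrices, moving the
#'     conditional entropy monotonically; the two voices' temperatures are
#'     drawn through a Gaussian copula with correlation `rho`, so `rho`
#'     controls how strongly melody and bass uncertainty co-vary across
#'     units.
#' }
#' The returned object carries the true matrices and their analytic
#' conditional entropies, so estimation error and correlation recovery can
#' be measured exactly.
#'
#' Defaults mirror a sonata-cycle-sized study: 32 aggregation units, one
#' piece per unit, 5000 tones per voice, a first-order source over the
#' two-octave interval alphabet -12..12.
#'
#' @param nUnits number of aggregation units (pieces).
#' @param tonesPerVoice tones per voice line (intervals + 1).
#' @param order order of the true interval sources (0..5; alphabet^order
#'   contexts must stay below 2^20).
#' @param alphabet integer interval alphabet.
#' @param baseConcentration Dirichlet concentration of the shared base rows.
#' @param voicePerturbation mixing weight in [0, 1] of the voice/unit
#'   perturbations (0 = all pieces and voices share the base exactly).
#' @param rho cross-voice correlation of the per-unit log-temperatures, in
#'   [-1, 1].
#' @param temperatureRange positive length-2 interval; per-unit temperatures
#'   are log-uniform over it (a degenerate interval fixes T).
#' @param modes `"alternate"` (units alternate major/minor), `"paired"`
#'   (requires `nUnits = 24`; one major and one minor unit per tonic, named
#'   like `"C_major"`), `"major"`, or `"minor"`.
#' @param seed integer seed; all randomness flows from it.
#' @param bassStart,melodyOffset starting MIDI pitch of the bass line and
#'   the melody's offset above it.
#' @param pitchRange optional length-2 bounds; exceeding them aborts with
#'   advice to widen the range (pitch level does not affect the
#'   interval-based analysis, so the default is unbounded).
#' @return A [SyntheticCorpus-class].
#' @export
#' @examples
#' sc <- syntheticCorpus(nUnits = 4, tonesPerVoice = 200, alphabet = -4:4,
#'                       seed = 1)
#' analyticH(sc)[1:4, ]
syntheticCorpus <- function(nUnits = 32L, tonesPerVoice = 5000L, order = 1L,
                            alphabet = -12:12, baseConcentration = 1,
                            voicePerturbation = 0.3, rho = 0.8,
                            temperatureRange = c(0.5, 2),
                            modes = c("alternate", "paired", "major",
                                      "minor"),
                            seed, bassStart = 48L, melodyOffset = 24L,
                            pitchRange = NULL) {
  modes <- match.arg(modes)
  if (missing(seed)) .stopf("a seed is required; all randomness flows from it")
  order <- as.integer(order)
  alphabet <- as.integer(alphabet)
  nA <- length(alphabet)
  if (nA == 0L) .stopf("interval alphabet must be non-empty")
  if (anyDuplicated(alphabet)) .stopf("interval alphabet has duplicates")
  if (order < 0L || order > 5L) .stopf("order must be in 0..5")
  nCtx <- if (order == 0L) 1L else nA^order
  if (nCtx * nA > 2^20)
    .stopf("alphabet^order too large (%d rows); use a smaller alphabet or order",
           nCtx)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    .stopf("rho must be a single value in [-1, 1]")
  if (length(temperatureRange) != 2L || any(temperatureRange <= 0))
    .stopf("temperatureRange must be two positive values")
  temperatureRange <- sort(temperatureRange)
  if (voicePerturbation < 0 || voicePerturbation > 1)
    .stopf("voicePerturbation must lie in [0, 1]")
  if (tonesPerVoice <= order + 1L)
    .stopf("tonesPerVoice must exceed order + 1")
  if (modes == "paired" && nUnits != 24L)
    .stopf("modes = 'paired' requires nUnits = 24 (12 tonics x 2 modes)")

  unitIdsV <- switch(modes,
    paired = paste0(rep(.tonics, each = 2), "_",
                    rep(c("major", "minor"), 12)),
    sprintf("unit%02d", seq_len(nUnits)))
  modeV <- switch(modes,
    paired = rep(c("major", "minor"), 12),
    alternate = rep(c("major", "minor"), length.out = nUnits),
    major = rep("major", nUnits),
    minor = rep("minor", nUnits))

  set.seed(as.integer(seed))
  eps <- voicePerturbation
  base <- .rdirichlet(nCtx, nA, baseConcentration)
  voiceNoise <- list(melody = .rdirichlet(nCtx, nA, 1),
                     bass = .rdirichlet(nCtx, nA, 1))
  unitNoise <- lapply(seq_len(nUnits), function(u)
    list(melody = .rdirichlet(nCtx, nA, 1), bass = .rdirichlet(nCtx, nA, 1)))
  z1 <- stats::rnorm(nUnits)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nUnits)
  lt <- log(temperatureRange)
  temp <- list(melody = exp(lt[1] + stats::pnorm(z1) * diff(lt)),
               bass = exp(lt[1] + stats::pnorm(z2) * diff(lt)))

  lines <- list(); trueTP <- list(); hRows <- list()
  for (u in seq_len(nUnits)) {
    trueTP[[unitIdsV[u]]] <- list()
    for (v in .VOICES) {
      M <- (1 - eps) * base +
        eps * (0.5 * voiceNoise[[v]] + 0.5 * unitNoise[[u]][[v]])
      M <- M^(1 / temp[[v]][u])
      M <- M / rowSums(M)
      dimnames(M) <- list(NULL, alphabet)
      trueTP[[unitIdsV[u]]][[v]] <- M
      hRows[[length(hRows) + 1L]] <- data.frame(
        unit_id = unitIdsV[u], voice = v, mode = modeV[u], order = order,
        H_bits = analyticEntropy(if (order == 0L) as.vector(M) else M,
                                 order),
        stringsAsFactors = FALSE)
      d <- sampleIntervalChain(if (order == 0L) as.vector(M) else M,
                               tonesPerVoice - 1L, alphabet, order)
      start <- if (v == "melody") bassStart + melodyOffset else bassStart
      p <- as.integer(start + cumsum(c(0L, d)))
      if (!is.null(pitchRange) &&
          (min(p) < pitchRange[1] || max(p) > pitchRange[2]))
        .stopf("unit %s %s line leaves pitch range [%d, %d] (span %d..%d); widen the range or use a smaller/more balanced alphabet",
               unitIdsV[u], v, pitchRange[1], pitchRange[2], min(p), max(p))
      lines[[length(lines) + 1L]] <- VoiceLine(
        p, pieceId = unitIdsV[u], unitId = unitIdsV[u], voice = v,
        mode = modeV[u])
    }
  }

  manifest <- data.frame(piece_id = unitIdsV, unit_id = unitIdsV,
                         mode = modeV, stringsAsFactors = FALSE)
  new("SyntheticCorpus", lines = lines, manifest = manifest,
      trueTP = trueTP, analyticH = do.call(rbind, hRows),
      params = list(nUnits = nUnits, tonesPerVoice = tonesPerVoice,
                    order = order, alphabet = alphabet,
                    baseConcentration = baseConcentration,
                    voicePerturbation = voicePerturbation, rho = rho,
                    temperatureRange = temperatureRange, modes = modes,
                    seed = seed))
}
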