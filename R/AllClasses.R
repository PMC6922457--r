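#' @import methods
NULL

.VOICES <- c("melody", "bass")
.MODES <- c("major", "minor", "unknown")

#' ScoreEvents: onset-ordered sounding-pitch events of one score
#'
#' One event per onset at which at least one non-grace note begins. The pitch
#' set of an event contains every distinct non-grace pitch sounding at that
#' onset, including notes sustained from earlier onsets; tied continuations do
#' not open new events. Onsets are exact multiples of \code{1/divisions}
#' quarter notes.
#'
#' @slot onsets numeric, onset time of each event in quarter notes, ascending.
#' @slot pitches list of integer vectors, the sounding MIDI pitch set per
#'   event (middle C = 60), each sorted ascending with duplicates removed.
#' @slot divisions integer, ticks per quarter note used to represent onsets
#'   exactly.
#' @slot stats list of per-file parse counters (grace notes dropped,
#'   duplicate simultaneous pitches collapsed, unpitched notes skipped).
#' @exportClass ScoreEvents
setClass("ScoreEvents",
  representation(
    onsets = "numeric",
    pitches = "list",
    divisions = "integer",
    stats = "list"
  ),
  prototype(onsets = numeric(0), pitches = list(), divisions = 1L,
            stats = list())
)

setValidity("ScoreEvents", function(object) {
  msg <- character(0)
  if (length(object@onsets) != length(object@pitches))
    msg <- c(msg, "onsets and pitches must have equal length")
  if (is.unsorted(object@onsets, strictly = TRUE) &&
      length(object@onsets) > 1)
    msg <- c(msg, "onsets must be strictly increasing")
  bad <- vapply(object@pitches, function(p)
    length(p) == 0L || anyDuplicated(p) > 0L, logical(1))
  if (any(bad))
    msg <- c(msg, "every event must hold a non-empty duplicate-free pitch set")
  if (length(msg)) msg else TRUE
})

#' VoiceLine: the ordered pitch sequence of one piece and one voice role
#'
#' A melody line holds the per-event maximum pitch, a bass line the per-event
#' minimum, of the piece's \linkS4class{ScoreEvents}. Consecutive repeated
#' pitches are retained (they encode the unison interval 0).
#'
#' @slot pieceId character, identifier of the source piece (e.g. one sonata
#'   movement or one prelude).
#' @slot unitId character, aggregation unit the piece belongs to (sonata
#'   number, key of a prelude/fugue group, ...).
#' @slot voice `"melody"` or `"bass"`.
#' @slot mode tonal mode label: `"major"`, `"minor"` or `"unknown"`.
#' @slot pitches integer vector of MIDI pitches (middle C = 60), length >= 1.
#' @exportClass VoiceLine
setClass("VoiceLine",
  representation(
    pieceId = "character",
    unitId = "character",
    voice = "character",
    mode = "character",
    pitches = "integer"
  )
)

setValidity("VoiceLine", function(object) {
  msg <- character(0)
  if (length(object@voice) != 1L || !object@voice %in% .VOICES)
    msg <- c(msg, "voice must be one of 'melody', 'bass'")
  if (length(object@mode) != 1L || !object@mode %in% .MODES)
    msg <- c(msg, "mode must be one of 'major', 'minor', 'unknown'")
  if (length(object@pitches) < 1L)
    msg <- c(msg, "pitches must contain at least one tone")
  if (anyNA(object@pitches))
    msg <- c(msg, "pitches must not contain NA")
  if (length(msg)) msg else TRUE
})

#' MusicCorpus: a collection of voice lines organised by a manifest
#'
#' Holds one melody and one bass \linkS4class{VoiceLine} per piece, together
#' with the manifest rows (piece id, aggregation unit, mode) that organise
#' them. Manifest order is preserved and defines unit order downstream.
#'
#' @slot lines list of \linkS4class{VoiceLine} objects.
#' @slot manifest data.frame with columns `piece_id`, `unit_id`, `mode` (and
#'   `path` when read from files), one row per piece, in manifest order.
#' @exportClass MusicCorpus
setClass("MusicCorpus",
  representation(lines = "list", manifest = "data.frame")
)

setValidity("MusicCorpus", function(object) {
  msg <- character(0)
  if (!all(vapply(object@lines, is, logical(1), "VoiceLine")))
    msg <- c(msg, "lines must all be VoiceLine objects")
  need <- c("piece_id", "unit_id", "mode")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, paste("manifest must have columns",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SyntheticCorpus: a generated corpus with known ground truth
#'
#' A \linkS4class{MusicCorpus} whose voice lines were sampled from known
#' interval Markov sources, carrying the true transition matrices and their
#' analytic conditional entropies alongside the sampled lines.
#'
#' @slot trueTP named list, per `unitId` a list with elements `melody` and
#'   `bass`, each a row-stochastic transition matrix over the interval
#'   alphabet (rows = contexts, columns = target intervals).
#' @slot analyticH data.frame with columns `unit_id`, `voice`, `mode`,
#'   `order`, `H_bits`: the conditional entropy of each true source evaluated
#'   at its stationary context distribution.
#' @slot params list, the generator settings used (including the seed).
#' @exportClass SyntheticCorpus
setClass("SyntheticCorpus",
  contains = "MusicCorpus",
  representation(trueTP = "list", analyticH = "data.frame", params = "list")
)

#' TPDistribution: an order-n transitional probability distribution
#'
#' Counts and conditional probabilities over (context pattern, target) pairs
#' at one Markov order, plus the marginal context distribution. Context
#' patterns are transposition-invariant interval encodings serialised as text
#' such as `"(4,7)"`; the empty context is `"()"`. Pooled distributions may
#' carry non-integer (weighted) counts.
#'
#' @slot order integer Markov order, 0..5.
#' @slot convention `"window"` or `"chain"` (see [contextTargets()]).
#' @slot transitions data.frame with columns `context` (character), `target`
#'   (integer), `count` (numeric), `prob` (numeric conditional probability
#'   P(target | context)).
#' @slot contexts data.frame with columns `context`, `count`, `prob` (the
#'   marginal probability of each context).
#' @slot nTransitions numeric, total number (or weighted mass) of observed
#'   transitions.
#' @exportClass TPDistribution
setClass("TPDistribution",
  representation(
    order = "integer",
    convention = "character",
    transitions = "data.frame",
    contexts = "data.frame",
    nTransitions = "numeric"
  )
)

setValidity("TPDistribution", function(object) {
  msg <- character(0)
  if (length(object@order) != 1L || is.na(object@order) ||
      object@order < 0L || object@order > 5L)
    msg <- c(msg, "order must be a single integer in 0..5")
  if (!object@convention %in% c("window", "chain"))
    msg <- c(msg, "convention must be 'window' or 'chain'")
  tr <- object@transitions
  cx <- object@contexts
  if (nrow(tr) > 0L) {
    s <- tapply(tr$prob, tr$context, sum)
    if (any(abs(s - 1) > 1e-12))
      msg <- c(msg, "conditional probabilities must sum to 1 per context")
    if (abs(sum(cx$prob) - 1) > 1e-12)
      msg <- c(msg, "context probabilities must sum to 1")
    rs <- tapply(tr$count, tr$context, sum)
    if (any(abs(rs[cx$context] - cx$count) > 1e-9 * pmax(1, cx$count)))
      msg <- c(msg, "context counts must equal summed transition counts")
  } else if (object@nTransitions != 0) {
    msg <- c(msg, "empty transition table requires nTransitions == 0")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: transition types by (unit, voice) variables
#'
#' The input to the principal component analysis: rows are transition-type
#' keys (`"context->target"`) at one order, columns are (aggregation unit,
#' voice) variables. Under `valueKind = "tp"` cells hold conditional
#' probabilities with 0 where a type was never observed in that column; under
#' `valueKind = "ic"` cells hold information content (bits) and rows are
#' restricted to types observed in every column.
#'
#' @slot values numeric matrix, transition types x variables.
#' @slot columnInfo data.frame with columns `unit_id`, `voice`, `mode`, one
#'   row per matrix column.
#' @slot order integer Markov order of the transition types.
#' @slot valueKind `"tp"` or `"ic"`.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    columnInfo = "data.frame",
    order = "integer",
    valueKind = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@values) != nrow(object@columnInfo))
    msg <- c(msg, "columnInfo must describe every column")
  if (!object@valueKind %in% c("tp", "ic"))
    msg <- c(msg, "valueKind must be 'tp' or 'ic'")
  if (object@valueKind == "tp") {
    if (any(object@values < 0 | object@values > 1))
      msg <- c(msg, "tp values must lie in [0, 1]")
    # an all-zero tp column means no observed transitions at all; under ic
    # a zero is a legitimate value (a certain transition)
    if (ncol(object@values) > 0 &&
        any(colSums(abs(object@values)) == 0))
      msg <- c(msg, "no column may be all zero")
  }
  if (length(msg)) msg else TRUE
})

#' PCAResult: correlation-matrix PCA of a feature matrix
#'
#' Eigen decomposition of the correlation matrix of the (unit, voice)
#' variables, with variance shares and per-variable loadings for the first
#' `nReport` components. Loadings are eigenvectors scaled by the square root
#' of their eigenvalue (variable-component correlations, in [-1, 1]); the
#' sign of each component is fixed so its mean loading is non-negative.
#'
#' @slot eigenvalues numeric, descending; sums to the number of variables.
#' @slot variancePct numeric, percentage of total variance per component.
#' @slot cumulativePct numeric, running sum of `variancePct`.
#' @slot loadings numeric matrix, variables x reported components.
#' @slot nAdopted integer, number of components with eigenvalue > 1.
#' @slot columnInfo data.frame describing the variables (`unit_id`, `voice`,
#'   `mode`).
#' @exportClass PCAResult
setClass("PCAResult",
  representation(
    eigenvalues = "numeric",
    variancePct = "numeric",
    cumulativePct = "numeric",
    loadings = "matrix",
    nAdopted = "integer",
    columnInfo = "data.frame"
  )
)

setValidity("PCAResult", function(object) {
  msg <- character(0)
  n <- length(object@eigenvalues)
  if (abs(sum(object@eigenvalues) - n) > 1e-8)
    msg <- c(msg, "eigenvalues must sum to the number of variables")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (is.unsorted(object@cumulativePct))
    msg <- c(msg, "cumulative variance must be non-decreasing")
  if (length(msg)) msg else TRUE
})
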