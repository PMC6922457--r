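#' Accessors for tonalEntropy classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `pitches()` returns the ordered pitch vector of a [VoiceLine-class] (or the
#' per-event pitch sets of a [ScoreEvents-class]); `pieceId()`, `unitId()`,
#' `voiceOf()` and `modeOf()` return the line's labels; `tpOrder()`,
#' `transitions()`, `contextProbs()` and `nTransitions()` expose a
#' [TPDistribution-class]; `eigenvalues()`, `variancePct()`, `loadings()` and
#' `nAdopted()` expose a [PCAResult-class]; `corpusLines()` and
#' `corpusManifest()` expose a [MusicCorpus-class]; `trueTP()` and
#' `analyticH()` expose the ground truth of a [SyntheticCorpus-class].
#'
#' @param x an object of the documented class.
#' @return The slot content named by the accessor.
#' @name accessors
#' @examples
#' vl <- VoiceLine(c(60L, 64L, 67L), voice = "melody")
#' pitches(vl)
#' voiceOf(vl)
NULL

#' @rdname accessors
#' @export
setGeneric("pitches", function(x) standardGeneric("pitches"))
#' @rdname accessors
#' @export
setGeneric("pieceId", function(x) standardGeneric("pieceId"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("voiceOf", function(x) standardGeneric("voiceOf"))
#' @rdname accessors
#' @export
setGeneric("modeOf", function(x) standardGeneric("modeOf"))
#' @rdname accessors
#' @export
setGeneric("tpOrder", function(x) standardGeneric("tpOrder"))
#' @rdname accessors
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
#' @rdname accessors
#' @export
setGeneric("contextProbs", function(x) standardGeneric("contextProbs"))
#' @rdname accessors
#' @export
setGeneric("nTransitions", function(x) standardGeneric("nTransitions"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("variancePct", function(x) standardGeneric("variancePct"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("nAdopted", function(x) standardGeneric("nAdopted"))
#' @rdname accessors
#' @export
setGeneric("corpusLines", function(x) standardGeneric("corpusLines"))
#' @rdname accessors
#' @export
setGeneric("corpusManifest", function(x) standardGeneric("corpusManifest"))
#' @rdname accessors
#' @export
setGeneric("trueTP", function(x) standardGeneric("trueTP"))
#' @rdname accessors
#' @export
setGeneric("analyticH", function(x) standardGeneric("analyticH"))

#' @rdname accessors
setMethod("pitches", "VoiceLine", function(x) x@pitches)
#' @rdname accessors
setMethod("pitches", "ScoreEvents", function(x) x@pitches)
#' @rdname accessors
setMethod("pieceId", "VoiceLine", function(x) x@pieceId)
#' @rdname accessors
setMethod("unitId", "VoiceLine", function(x) x@unitId)
#' @rdname accessors
setMethod("voiceOf", "VoiceLine", function(x) x@voice)
#' @rdname accessors
setMethod("modeOf", "VoiceLine", function(x) x@mode)
#' @rdname accessors
setMethod("tpOrder", "TPDistribution", function(x) x@order)
#' @rdname accessors
setMethod("transitions", "TPDistribution", function(x) x@transitions)
#' @rdname accessors
setMethod("contextProbs", "TPDistribution", function(x) x@contexts)
#' @rdname accessors
setMethod("nTransitions", "TPDistribution", function(x) x@nTransitions)
#' @rdname accessors
setMethod("eigenvalues", "PCAResult", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("variancePct", "PCAResult", function(x) x@variancePct)
#' @rdname accessors
setMethod("loadings", "PCAResult", function(x) x@loadings)
#' @rdname accessors
setMethod("nAdopted", "PCAResult", function(x) x@nAdopted)
#' @rdname accessors
setMethod("corpusLines", "MusicCorpus", function(x) x@lines)
#' @rdname accessors
setMethod("corpusManifest", "MusicCorpus", function(x) x@manifest)
#' @rdname accessors
setMethod("trueTP", "SyntheticCorpus", function(x) x@trueTP)
#' @rdname accessors
setMethod("analyticH", "SyntheticCorpus", function(x) x@analyticH)

#' @describeIn accessors number of events in a score
#' @export
setMethod("length", "ScoreEvents", function(x) length(x@onsets))
#' @describeIn accessors number of tones in a voice line
#' @export
setMethod("length", "VoiceLine", function(x) length(x@pitches))
#' @describeIn accessors number of pieces in a corpus
#' @export
setMethod("length", "MusicCorpus", function(x) nrow(x@manifest))

setMethod("show", "ScoreEvents", function(object) {
  cat(sprintf("ScoreEvents: %d events, %s ticks/quarter\n",
              length(object@onsets), object@divisions))
  if (length(object@stats))
    cat(sprintf("  parse: %d grace dropped, %d duplicates collapsed, %d unpitched skipped\n",
                object@stats$graceDropped %||% 0L,
                object@stats$duplicatesCollapsed %||% 0L,
                object@stats$unpitchedSkipped %||% 0L))
})

setMethod("show", "VoiceLine", function(object) {
  p <- object@pitches
  head <- paste(utils::head(p, 8), collapse = " ")
  cat(sprintf("VoiceLine '%s' (%s, %s, unit '%s'): %d tones [%s%s]\n",
              object@pieceId, object@voice, object@mode, object@unitId,
              length(p), head, if (length(p) > 8) " ..." else ""))
})

setMethod("show", "MusicCorpus", function(object) {
  m <- object@manifest
  cat(sprintf("MusicCorpus: %d pieces in %d units (%d voice lines)\n",
              nrow(m), length(unique(m$unit_id)), length(object@lines)))
})

setMethod("show", "SyntheticCorpus", function(object) {
  callNextMethod()
  p <- object@params
  cat(sprintf("  synthetic: order %d on alphabet of %d intervals, rho = %.2f, seed = %s\n",
              p$order, length(p$alphabet), p$rho, p$seed))
})

setMethod("show", "TPDistribution", function(object) {
  cat(sprintf("TPDistribution: order %d (%s), %d contexts, %d transition types, n = %s\n",
              object@order, object@convention, nrow(object@contexts),
              nrow(object@transitions), format(object@nTransitions)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s, order %d): %d transition types x %d (unit, voice) variables\n",
              object@valueKind, object@order,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d variables, %d components with eigenvalue > 1\n",
              length(object@eigenvalues), object@nAdopted))
  k <- min(ncol(object@loadings), length(object@eigenvalues))
  for (i in seq_len(k))
    cat(sprintf("  PC%d: eigenvalue %.3f, %.2f%% (cum. %.2f%%)\n",
                i, object@eigenvalues[i], object@variancePct[i],
                object@cumulativePct[i]))
})
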