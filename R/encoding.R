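#' Encode a tone window as a transposition-invariant interval pattern
#'
#' An order-n pattern is an (n+1)-tone window re-based on its first pitch:
#' the encoding is the signed semitone offset of every later tone relative to
#' tone 1 (+1 per semitone up, -1 per semitone down). Any constant
#' transposition of the window yields the same pattern, which removes the
#' effect of key changes on transition statistics.
#'
#' @param pitches integer vector of n+1 >= 2 MIDI pitches.
#' @return Integer vector of n offsets.
#' @export
#' @examples
#' encodeWindow(c(60, 64, 67))  # 4 7
#' encodeWindow(c(62, 66, 69))  # 4 7 (transposition invariant)
encodeWindow <- function(pitches) {
  if (length(pitches) < 2L)
    .stopf("degenerate window: need at least 2 tones, got %d",
           length(pitches))
  as.integer(pitches[-1L] - pitches[1L])
}

#' Enumerate order-n context/target pairs of a voice line
#'
#' Slides an order-n window along the line and returns one (context, target)
#' pair per position, in the transposition-invariant interval encoding.
#'
#' Under the default `"window"` convention, events are tones: the context is
#' the interval encoding of the n preceding tones (n-1 offsets relative to
#' the first context tone) and the target is the offset of the new tone
#' relative to that same first context tone. A single preceding tone carries
#' no transposition-invariant information, so its context is the empty
#' pattern `"()"`; order 0 is defined as the marginal distribution of
#' elementary intervals (2-tone windows), which keeps it key-invariant.
#' A line of L tones yields `max(0, L - max(order, 1))` pairs.
#'
#' Under the `"chain"` convention, events are elementary intervals
#' `d[t] = p[t+1] - p[t]`: the context is the n preceding intervals and the
#' target the next interval, giving `max(0, L - 1 - order)` pairs.
#'
#' @param line a [VoiceLine-class] or a bare integer pitch vector.
#' @param order Markov order, 0..5.
#' @param convention `"window"` or `"chain"`.
#' @param quiet suppress the too-short-line warning.
#' @return data.frame with character column `context` (serialised pattern,
#'   `"()"` when empty) and integer column `target`; zero rows (with a
#'   warning) when the line is too short for the requested order.
#' @export
#' @examples
#' contextTargets(c(60L, 62L, 64L), order = 2)   # context "(2)", target 4
#' contextTargets(c(60L, 62L, 64L), order = 0)   # targets 2, 2
contextTargets <- function(line, order, convention = c("window", "chain"),
                           quiet = FALSE) {
  convention <- match.arg(convention)
  p <- if (is(line, "VoiceLine")) line@pitches else as.integer(line)
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 0L || order > 5L)
    .stopf("order must be a single integer in 0..5")
  empty <- data.frame(context = character(0), target = integer(0),
                      stringsAsFactors = FALSE)
  L <- length(p)

  if (convention == "window") {
    span <- max(order, 1L) + 1L # tones per window
    if (L < span) {
      if (!quiet)
        .warnf("line of %d tones is shorter than an order-%d window (%d tones); contributing nothing",
               L, order, span)
      return(empty)
    }
    if (order <= 1L) {
      return(data.frame(context = "()", target = diff(p),
                        stringsAsFactors = FALSE))
    }
    E <- embed(p, order + 1L) # row t: p[t], p[t-1], ..., p[t-order]
    base <- E[, order + 1L]
    ctx <- E[, order:2L, drop = FALSE] - base
    data.frame(context = .patternKeys(ctx), target = E[, 1L] - base,
               stringsAsFactors = FALSE)
  } else {
    d <- diff(p)
    if (length(d) < order + 1L) {
      if (!quiet)
        .warnf("line of %d tones has fewer than %d elementary intervals; contributing nothing at order %d",
               L, order + 1L, order)
      return(empty)
    }
    if (order == 0L)
      return(data.frame(context = "()", target = d, stringsAsFactors = FALSE))
    E <- embed(d, order + 1L)
    ctx <- E[, (order + 1L):2L, drop = FALSE]
    data.frame(context = .patternKeys(ctx), target = E[, 1L],
               stringsAsFactors = FALSE)
  }
}
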