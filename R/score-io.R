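#' Parse a MusicXML score into onset events
#'
#' Reads a (partwise or timewise, uncompressed) MusicXML file and returns the
#' time-ordered sounding-pitch events of the whole score. An event is opened
#' at every onset at which at least one non-grace note begins; its pitch set
#' is every distinct non-grace pitch sounding at that onset, including notes
#' held over from earlier onsets. Grace notes are excluded entirely, tied
#' continuations do not open new events (a tie chain is a single playable
#' note), equivalent simultaneous pitches are counted once, and rests
#' generate no events. Onsets are tracked as exact integer ticks (a common
#' multiple of every `<divisions>` value in the file), so part order and the
#' partwise/timewise dialect cannot change the result.
#'
#' @param path path to a `.xml`/`.musicxml` file.
#' @param quiet suppress the per-file parse summary written to stderr.
#' @return A [ScoreEvents-class] object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeMusicXMLFixture(c(67L, 69L), c(48L, 50L), f)
#' parseScore(f, quiet = TRUE)
parseScore <- function(path, quiet = FALSE) {
  if (!file.exists(path)) .stopf("score file does not exist: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    .stopf("malformed XML in %s: %s", path, conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (!root %in% c("score-partwise", "score-timewise"))
    .stopf("%s: root element <%s> is not a MusicXML score", path, root)

  divs <- as.integer(xml2::xml_text(xml2::xml_find_all(doc, ".//divisions")))
  divs <- divs[!is.na(divs) & divs > 0L]
  ticksPerQuarter <- if (length(divs)) Reduce(.lcm2, unique(divs)) else 1L

  # Collect, per part id, the measure nodes in document order; this
  # normalises the partwise and timewise dialects into one traversal.
  chunks <- list() # partId -> list of measure-level nodes
  if (root == "score-partwise") {
    for (part in xml2::xml_find_all(doc, "./part")) {
      pid <- xml2::xml_attr(part, "id")
      chunks[[pid]] <- xml2::xml_find_all(part, "./measure")
    }
  } else {
    for (meas in xml2::xml_find_all(doc, "./measure")) {
      for (part in xml2::xml_find_all(meas, "./part")) {
        pid <- xml2::xml_attr(part, "id")
        chunks[[pid]] <- c(chunks[[pid]], list(part))
      }
    }
  }
  if (length(chunks) == 0L) .stopf("%s: score contains no parts", path)

  onset <- integer(0); end <- integer(0); pitch <- integer(0)
  newOnset <- logical(0)
  nGrace <- 0L; nUnpitched <- 0L

  stepBase <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

  for (pid in names(chunks)) {
    division <- 1L
    cursor <- 0L
    lastOnset <- 0L
    for (meas in chunks[[pid]]) {
      measureMax <- cursor
      for (node in xml2::xml_children(meas)) {
        nm <- xml2::xml_name(node)
        if (nm == "attributes") {
          d <- xml2::xml_text(xml2::xml_find_first(node, "./divisions"))
          if (!is.na(d) && as.integer(d) > 0L) division <- as.integer(d)
        } else if (nm == "backup" || nm == "forward") {
          d <- xml2::xml_text(xml2::xml_find_first(node, "./duration"))
          d <- if (is.na(d)) 0L else as.integer(d)
          ticks <- d * (ticksPerQuarter %/% division)
          cursor <- cursor + if (nm == "backup") -ticks else ticks
        } else if (nm == "note") {
          isGrace <- !is.na(xml2::xml_find_first(node, "./grace"))
          isChord <- !is.na(xml2::xml_find_first(node, "./chord"))
          isRest <- !is.na(xml2::xml_find_first(node, "./rest"))
          d <- xml2::xml_text(xml2::xml_find_first(node, "./duration"))
          d <- if (is.na(d)) 0L else as.integer(d)
          ticks <- d * (ticksPerQuarter %/% division)
          at <- if (isChord) lastOnset else cursor
          tieStop <- !is.na(xml2::xml_find_first(
            node, "./tie[@type='stop']")) ||
            !is.na(xml2::xml_find_first(
              node, "./notations/tied[@type='stop']"))
          if (isGrace) {
            nGrace <- nGrace + 1L
          } else if (!isRest) {
            pnode <- xml2::xml_find_first(node, "./pitch")
            if (is.na(pnode)) {
              nUnpitched <- nUnpitched + 1L
            } else {
              step <- xml2::xml_text(xml2::xml_find_first(pnode, "./step"))
              alter <- xml2::xml_text(xml2::xml_find_first(pnode, "./alter"))
              octave <- xml2::xml_text(xml2::xml_find_first(pnode, "./octave"))
              if (is.na(step) || is.na(octave) || !step %in% names(stepBase))
                .stopf("%s: <note> with incomplete <pitch> element", path)
              midi <- (as.integer(octave) + 1L) * 12L + stepBase[[step]] +
                (if (is.na(alter)) 0L else as.integer(round(as.numeric(alter))))
              onset <- c(onset, at)
              end <- c(end, at + max(ticks, 0L))
              pitch <- c(pitch, midi)
              newOnset <- c(newOnset, !tieStop)
            }
          }
          if (!isChord && !isGrace) {
            lastOnset <- cursor
            cursor <- cursor + ticks
          }
          if (cursor > measureMax) measureMax <- cursor
        }
        if (cursor > measureMax) measureMax <- cursor
      }
      cursor <- measureMax
    }
  }

  if (nUnpitched > 0L && !quiet)
    .msgf("%s: skipped %d unpitched/percussion notes", basename(path),
          nUnpitched)
  if (length(onset) == 0L || !any(newOnset)) {
    if (!quiet) .msgf("%s: no pitched events", basename(path))
    return(new("ScoreEvents", onsets = numeric(0), pitches = list(),
               divisions = as.integer(ticksPerQuarter),
               stats = list(graceDropped = nGrace, duplicatesCollapsed = 0L,
                            unpitchedSkipped = nUnpitched)))
  }

  eventTicks <- sort(unique(onset[newOnset]))
  # For every sounding note, the range of event onsets it covers:
  # events e with onset(note) <= t_e < end(note) (or t_e == onset for
  # zero-length notes in malformed files).
  lo <- findInterval(onset - 0.5, eventTicks) + 1L
  hi <- pmax(findInterval(end - 0.5, eventTicks), lo - 1L)
  hi <- pmax(hi, ifelse(onset %in% eventTicks, lo, lo - 1L))
  keep <- lo <= hi
  counts <- hi[keep] - lo[keep] + 1L
  evIdx <- sequence(counts) - 1L + rep(lo[keep], counts)
  evPitch <- rep(pitch[keep], counts)
  sets <- lapply(split(evPitch, factor(evIdx, levels = seq_along(eventTicks))),
                 function(p) sort(unique(p)))
  nDup <- length(evPitch) - sum(lengths(sets))
  names(sets) <- NULL

  empty <- lengths(sets) == 0L
  if (any(empty)) { # can only arise from degenerate zero-length notes
    sets <- sets[!empty]
    eventTicks <- eventTicks[!empty]
  }

  if (!quiet)
    .msgf("%s: %d events, %d grace notes dropped, %d duplicate pitches collapsed",
          basename(path), length(eventTicks), nGrace, nDup)

  new("ScoreEvents", onsets = eventTicks / ticksPerQuarter, pitches = sets,
      divisions = as.integer(ticksPerQuarter),
      stats = list(graceDropped = nGrace, duplicatesCollapsed = nDup,
                   unpitchedSkipped = nUnpitched))
}

#' Extract the melody or bass line from score events
#'
#' The melody line is the highest, the bass line the lowest, pitch of every
#' event — the pitches that can be played at each point in time. Consecutive
#' equal pitches are retained; they later encode the unison interval 0.
#'
#' @param events a [ScoreEvents-class] object.
#' @param which `"melody"` (per-event maximum) or `"bass"` (minimum).
#' @param pieceId,unitId,mode labels attached to the returned line.
#' @return A [VoiceLine-class] of the same length as `events`.
#' @export
#' @examples
#' ev <- new("ScoreEvents", onsets = 0:2, divisions = 1L,
#'           pitches = list(c(60L, 64L, 67L), c(59L, 62L, 67L), c(60L, 64L)))
#' pitches(extractVoice(ev, "melody"))  # 67 67 64
#' pitches(extractVoice(ev, "bass"))    # 60 59 60
extractVoice <- function(events, which = c("melody", "bass"), pieceId = "",
                         unitId = "", mode = "unknown") {
  which <- match.arg(which)
  stopifnot(is(events, "ScoreEvents"))
  if (length(events) == 0L)
    .stopf("empty piece%s: no events to extract a %s line from",
           if (nzchar(pieceId)) paste0(" '", pieceId, "'") else "", which)
  f <- if (which == "melody") max else min
  VoiceLine(vapply(events@pitches, f, integer(1)), pieceId = pieceId,
            unitId = unitId, voice = which, mode = mode)
}

#' Read a corpus manifest
#'
#' @param path CSV file with header `path,piece_id,unit_id,mode`. Relative
#'   score paths are resolved against the manifest's directory.
#' @return A validated data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest does not exist: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("path", "piece_id", "unit_id", "mode")
  if (!all(need %in% names(m)))
    .stopf("manifest must have columns %s", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  .validateManifest(m)
  m
}

.validateManifest <- function(m) {
  if (any(!nzchar(m$unit_id)))
    .stopf("manifest rows with empty unit_id: %s",
           paste(which(!nzchar(m$unit_id)), collapse = ", "))
  bad <- !m$mode %in% .MODES
  if (any(bad))
    .stopf("invalid mode label(s): %s (must be major, minor or unknown)",
           paste(unique(m$mode[bad]), collapse = ", "))
  missing <- m$path[!file.exists(m$path)]
  if (length(missing))
    .stopf("manifest references missing file(s):\n  %s",
           paste(missing, collapse = "\n  "))
  invisible(m)
}

#' Load a corpus of scores as melody and bass voice lines
#'
#' Parses every file in the manifest and extracts one melody and one bass
#' [VoiceLine-class] per piece, tagged with the manifest's aggregation unit
#' and mode labels. Grouping by unit preserves manifest order. Mode labels
#' are taken from the manifest only, never inferred from key signatures.
#'
#' @param manifest a manifest path or a data.frame with columns
#'   `path`, `piece_id`, `unit_id`, `mode`.
#' @param onParseError `"abort"` (default) stops on the first unparsable
#'   file; `"skip"` drops the piece with a warning.
#' @param pitchRange length-2 integer vector; extracted pitches outside this
#'   keyboard range raise an error. `NULL` disables the check. Default is
#'   the 88-key piano range, MIDI 21..108.
#' @param quiet suppress per-file parse summaries.
#' @return A [MusicCorpus-class].
#' @export
loadCorpus <- function(manifest, onParseError = c("abort", "skip"),
                       pitchRange = c(21L, 108L), quiet = FALSE) {
  onParseError <- match.arg(onParseError)
  m <- if (is.character(manifest)) readManifest(manifest)
       else .validateManifest(as.data.frame(manifest))
  lines <- list()
  kept <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ev <- tryCatch(parseScore(m$path[i], quiet = quiet), error = function(e) {
      if (onParseError == "abort") stop(e)
      .warnf("skipping %s: %s", m$path[i], conditionMessage(e))
      NULL
    })
    if (is.null(ev) || length(ev) == 0L) {
      if (!is.null(ev))
        .warnf("skipping %s: no pitched events", m$path[i])
      next
    }
    kept[i] <- TRUE
    for (v in .VOICES) {
      vl <- extractVoice(ev, v, pieceId = m$piece_id[i],
                         unitId = m$unit_id[i], mode = m$mode[i])
      if (!is.null(pitchRange)) {
        out <- vl@pitches < pitchRange[1] | vl@pitches > pitchRange[2]
        if (any(out))
          .stopf("piece '%s': %d pitches outside the configured range [%d, %d]",
                 m$piece_id[i], sum(out), pitchRange[1], pitchRange[2])
      }
      lines[[length(lines) + 1L]] <- vl
    }
  }
  new("MusicCorpus", lines = lines, manifest = m[kept, , drop = FALSE])
}

#' Voice lines of a corpus, optionally filtered
#'
#' @param corpus a [MusicCorpus-class].
#' @param unit,voice optional `unit_id` / voice filters.
#' @return A list of [VoiceLine-class] objects in manifest order.
#' @export
linesFor <- function(corpus, unit = NULL, voice = NULL) {
  stopifnot(is(corpus, "MusicCorpus"))
  sel <- corpus@lines
  if (!is.null(unit))
    sel <- Filter(function(l) l@unitId %in% unit, sel)
  if (!is.null(voice))
    sel <- Filter(function(l) l@voice %in% voice, sel)
  sel
}

#' Unit ids of a corpus in manifest order
#' @param corpus a [MusicCorpus-class].
#' @return Character vector of unique `unit_id`s.
#' @export
unitIds <- function(corpus) unique(corpus@manifest$unit_id)
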