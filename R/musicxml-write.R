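.NOTE_STEPS <- c("C", "C", "D", "D", "E", "F", "F", "G", "G", "A", "A", "B")
.NOTE_ALTER <- c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)

.pitchXML <- function(midi, indent = "        ") {
  pc <- midi %% 12L
  octave <- midi %/% 12L - 1L
  alter <- .NOTE_ALTER[pc + 1L]
  paste0(indent, "<pitch><step>", .NOTE_STEPS[pc + 1L], "</step>",
         if (alter != 0L) paste0("<alter>", alter, "</alter>") else "",
         "<octave>", octave, "</octave></pitch>")
}

.noteXML <- function(midi, duration, grace = FALSE, chord = FALSE,
                     tie = NULL) {
  parts <- c("      <note>",
             if (grace) "        <grace/>",
             if (chord) "        <chord/>",
             .pitchXML(midi),
             if (!grace) paste0("        <duration>", duration,
                                "</duration>"),
             if (!is.null(tie))
               paste0("        <tie type=\"", tie, "\"/>"))
  c(parts, "      </note>")
}

#' Write a minimal two-part MusicXML fixture
#'
#' Emits a partwise score with the melody in part P1 and the bass in part
#' P2, one quarter-note per event in 4/4 measures, so that
#' `parseScore()` followed by `extractVoice()` recovers the two pitch lists
#' exactly. Optional decorations exercise the parser's event rules without
#' changing the recovered lines: grace-note ornaments (excluded by the
#' event rules), unison doubling of the melody pitch inside the bass part
#' (collapsed as an equivalent simultaneous pitch), and splitting a melody
#' note into a tied pair (a tie chain is a single event).
#'
#' @param melody,bass equal-length integer MIDI pitch vectors with
#'   `melody >= bass` at every index (the per-event maximum/minimum rule
#'   could not recover crossing lines).
#' @param path output file path.
#' @param graceAt indices before which to insert a grace-note ornament.
#' @param unisonAt indices at which the bass part doubles the melody pitch
#'   as a chord note.
#' @param tieSplitAt indices whose melody note is written as two tied
#'   eighth notes.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeMusicXMLFixture(c(67L, 69L, 67L), c(48L, 50L, 52L), f,
#'                      graceAt = 2, unisonAt = 3)
writeMusicXMLFixture <- function(melody, bass, path, graceAt = integer(0),
                                 unisonAt = integer(0),
                                 tieSplitAt = integer(0)) {
  melody <- as.integer(melody); bass <- as.integer(bass)
  if (length(melody) != length(bass))
    .stopf("melody and bass must have equal length")
  if (length(melody) == 0L) .stopf("cannot write an empty fixture")
  if (any(melody < bass))
    .stopf("melody must stay at or above the bass at every event (crossing at index %d)",
           which(melody < bass)[1])
  if (any(melody < 12L) || any(melody > 127L) ||
      any(bass < 12L) || any(bass > 127L))
    .stopf("pitches must lie in MIDI 12..127 to be representable")

  div <- 2L # ticks per quarter, so a tied pair of eighths fits one slot
  perMeasure <- 4L
  n <- length(melody)
  nMeas <- ceiling(n / perMeasure)

  partBody <- function(pitchesV, isMelody) {
    out <- character(0)
    for (m in seq_len(nMeas)) {
      out <- c(out, paste0("    <measure number=\"", m, "\">"))
      if (m == 1L)
        out <- c(out,
          "      <attributes>",
          paste0("        <divisions>", div, "</divisions>"),
          "        <time><beats>4</beats><beat-type>4</beat-type></time>",
          "      </attributes>")
      for (k in seq_len(perMeasure)) {
        i <- (m - 1L) * perMeasure + k
        if (i > n) {
          out <- c(out, "      <note>",
                   paste0("        <rest/>"),
                   paste0("        <duration>", div, "</duration>"),
                   "      </note>")
          next
        }
        if (isMelody && i %in% graceAt)
          out <- c(out, .noteXML(pitchesV[i] + 2L, 0L, grace = TRUE))
        if (isMelody && i %in% tieSplitAt) {
          out <- c(out, .noteXML(pitchesV[i], div %/% 2L, tie = "start"),
                   .noteXML(pitchesV[i], div %/% 2L, tie = "stop"))
        } else {
          out <- c(out, .noteXML(pitchesV[i], div))
          if (!isMelody && i %in% unisonAt && melody[i] != pitchesV[i]) {
            # double the melody pitch inside the bass part at this onset
            out <- c(out, .noteXML(melody[i], div, chord = TRUE))
          }
        }
      }
      out <- c(out, "    </measure>")
    }
    out
  }

  xml <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<score-partwise version=\"3.1\">",
    "  <part-list>",
    "    <score-part id=\"P1\"><part-name>Melody</part-name></score-part>",
    "    <score-part id=\"P2\"><part-name>Bass</part-name></score-part>",
    "  </part-list>",
    "  <part id=\"P1\">",
    partBody(melody, TRUE),
    "  </part>",
    "  <part id=\"P2\">",
    partBody(bass, FALSE),
    "  </part>",
    "</score-partwise>")
  writeLines(xml, path)
  invisible(path)
}

#' Write a synthetic corpus as MusicXML files plus manifest
#'
#' Materialises every (melody, bass) pair of a corpus as a MusicXML file in
#' `dir` and writes `manifest.csv` referencing them, so the file-reading
#' path of the pipeline can be exercised end to end. When the corpus is
#' synthetic, the ground truth (analytic entropies) is written alongside as
#' `analytic_entropy.csv`.
#'
#' Voice lines whose melody would cross below the bass cannot be
#' represented by the per-event extraction rule; crossings are avoided at
#' generation time via `melodyOffset` (an error suggests raising it).
#'
#' @param corpus a [MusicCorpus-class] with one melody and one bass line per
#'   piece.
#' @param dir output directory, created if needed.
#' @param ... decoration arguments passed on to [writeMusicXMLFixture()].
#' @return The manifest data.frame, invisibly.
#' @export
writeCorpusFixtures <- function(corpus, dir, ...) {
  stopifnot(is(corpus, "MusicCorpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- corpus@manifest
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    mel <- linesFor(corpus, unit = m$unit_id[i], voice = "melody")
    bas <- linesFor(corpus, unit = m$unit_id[i], voice = "bass")
    mel <- Filter(function(l) l@pieceId == m$piece_id[i], mel)[[1]]
    bas <- Filter(function(l) l@pieceId == m$piece_id[i], bas)[[1]]
    paths[i] <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_",
                                           m$piece_id[i]), ".xml"))
    writeMusicXMLFixture(pitches(mel), pitches(bas), paths[i], ...)
  }
  out <- data.frame(path = paths, piece_id = m$piece_id,
                    unit_id = m$unit_id, mode = m$mode,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (is(corpus, "SyntheticCorpus"))
    utils::write.csv(corpus@analyticH, file.path(dir, "analytic_entropy.csv"),
                     row.names = FALSE)
  invisible(out)
}
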