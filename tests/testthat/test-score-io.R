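# Hand-written MusicXML snippets exercise the event rules one at a time;
# fixture-writer round trips are covered in test-synthetic.R.

noteXML <- function(step, octave, dur = 2, alter = NULL, chord = FALSE,
                    grace = FALSE, tie = NULL) {
  c("      <note>",
    if (grace) "        <grace/>",
    if (chord) "        <chord/>",
    paste0("        <pitch><step>", step, "</step>",
           if (!is.null(alter)) paste0("<alter>", alter, "</alter>"),
           "<octave>", octave, "</octave></pitch>"),
    if (!grace) paste0("        <duration>", dur, "</duration>"),
    if (!is.null(tie)) paste0("        <tie type=\"", tie, "\"/>"),
    "      </note>")
}

onePartScore <- function(measureBody, divisions = 2) {
  c(musicxmlHeader(),
    "  <part id=\"P1\">",
    "    <measure number=\"1\">",
    "      <attributes>",
    sprintf("        <divisions>%d</divisions>", divisions),
    "      </attributes>",
    measureBody,
    "    </measure>",
    "  </part>",
    "  <part id=\"P2\">",
    "    <measure number=\"1\">",
    noteXML("C", 3, dur = 8),
    "    </measure>",
    "  </part>",
    sprintf("</%s>", "score-partwise"))
}

test_that("a chord is one event holding all of its pitches", {
  f <- writeRawXML(onePartScore(c(
    noteXML("C", 4), noteXML("E", 4, chord = TRUE),
    noteXML("G", 4, chord = TRUE))))
  ev <- parseScore(f, quiet = TRUE)
  expect_equal(length(ev), 1L)
  expect_equal(pitches(ev)[[1]], c(48L, 60L, 64L, 67L)) # P2 sounds C3 too
})

test_that("grace notes are excluded from the event stream", {
  f <- writeRawXML(onePartScore(c(
    noteXML("A", 5, grace = TRUE), noteXML("G", 5, dur = 4),
    noteXML("F", 5, dur = 4))))
  ev <- parseScore(f, quiet = TRUE)
  expect_equal(vapply(pitches(ev), max, integer(1)), c(79L, 77L))
  expect_equal(ev@stats$graceDropped, 1L)
})

test_that("equivalent simultaneous pitches are counted once", {
  f <- writeRawXML(onePartScore(c(
    noteXML("C", 3, dur = 8)))) # P1 doubles the constant C3 in P2
  ev <- parseScore(f, quiet = TRUE)
  expect_equal(length(ev), 1L)
  expect_equal(pitches(ev)[[1]], 48L)
  expect_equal(ev@stats$duplicatesCollapsed, 1L)
})

test_that("a tie chain is a single event at the tie start", {
  f <- writeRawXML(onePartScore(c(
    noteXML("D", 5, dur = 4, tie = "start"),
    noteXML("D", 5, dur = 4, tie = "stop"))))
  ev <- parseScore(f, quiet = TRUE)
  expect_equal(length(ev), 1L)
  expect_true(74L %in% pitches(ev)[[1]])
})

test_that("sustained notes join the sounding set of later onsets", {
  # P1 holds G4 for a whole note while P2 attacks quarters; the held G4
  # must appear in every later event's pitch set
  lines <- c(musicxmlHeader(),
    "  <part id=\"P1\">",
    "    <measure number=\"1\">",
    "      <attributes><divisions>1</divisions></attributes>",
    noteXML("G", 4, dur = 4),
    "    </measure>",
    "  </part>",
    "  <part id=\"P2\">",
    "    <measure number=\"1\">",
    "      <attributes><divisions>1</divisions></attributes>",
    noteXML("C", 3, dur = 1), noteXML("D", 3, dur = 1),
    noteXML("E", 3, dur = 1), noteXML("F", 3, dur = 1),
    "    </measure>",
    "  </part>",
    "</score-partwise>")
  ev <- parseScore(writeRawXML(lines), quiet = TRUE)
  expect_equal(length(ev), 4L)
  expect_true(all(vapply(pitches(ev), function(p) 67L %in% p, logical(1))))
  expect_equal(pitches(extractVoice(ev, "bass")), c(48L, 50L, 52L, 53L))
})

test_that("rests generate no events and do not split the sequence", {
  f <- writeRawXML(onePartScore(c(
    noteXML("C", 5, dur = 2),
    "      <note><rest/><duration>4</duration></note>",
    noteXML("D", 5, dur = 2))))
  ev <- parseScore(f, quiet = TRUE)
  expect_equal(length(ev), 2L)
  expect_equal(ev@onsets, c(0, 3))
})

test_that("partwise and timewise dialects and part order are equivalent", {
  bodyA <- c("      <attributes><divisions>1</divisions></attributes>",
             noteXML("E", 5, dur = 1), noteXML("F", 5, dur = 1))
  bodyB <- c("      <attributes><divisions>1</divisions></attributes>",
             noteXML("C", 3, dur = 1), noteXML("B", 2, dur = 1))
  partwise <- c(musicxmlHeader(),
    "  <part id=\"P1\">", "    <measure number=\"1\">", bodyA,
    "    </measure>", "  </part>",
    "  <part id=\"P2\">", "    <measure number=\"1\">", bodyB,
    "    </measure>", "  </part>", "</score-partwise>")
  swapped <- c(musicxmlHeader(),
    "  <part id=\"P2\">", "    <measure number=\"1\">", bodyB,
    "    </measure>", "  </part>",
    "  <part id=\"P1\">", "    <measure number=\"1\">", bodyA,
    "    </measure>", "  </part>", "</score-partwise>")
  timewise <- c(musicxmlHeader("score-timewise"),
    "  <measure number=\"1\">",
    "    <part id=\"P1\">", bodyA, "    </part>",
    "    <part id=\"P2\">", bodyB, "    </part>",
    "  </measure>", "</score-timewise>")
  evP <- parseScore(writeRawXML(partwise), quiet = TRUE)
  evS <- parseScore(writeRawXML(swapped), quiet = TRUE)
  evT <- parseScore(writeRawXML(timewise), quiet = TRUE)
  expect_equal(pitches(evP), pitches(evS))
  expect_equal(pitches(evP), pitches(evT))
  expect_equal(evP@onsets, evT@onsets)
  expect_equal(pitches(extractVoice(evP, "melody")), c(76L, 77L))
  expect_equal(pitches(extractVoice(evP, "bass")), c(48L, 47L))
})

test_that("backup-based second voices land on the right onsets", {
  lines <- c(musicxmlHeader(),
    "  <part id=\"P1\">",
    "    <measure number=\"1\">",
    "      <attributes><divisions>1</divisions></attributes>",
    noteXML("G", 5, dur = 2), noteXML("A", 5, dur = 2),
    "      <backup><duration>4</duration></backup>",
    noteXML("C", 4, dur = 1), noteXML("D", 4, dur = 1),
    noteXML("E", 4, dur = 1), noteXML("F", 4, dur = 1),
    "    </measure>",
    "  </part>",
    "</score-partwise>")
  ev <- parseScore(writeRawXML(lines), quiet = TRUE)
  expect_equal(length(ev), 4L)
  expect_equal(pitches(extractVoice(ev, "melody")), c(79L, 79L, 81L, 81L))
  expect_equal(pitches(extractVoice(ev, "bass")), c(60L, 62L, 64L, 65L))
})

test_that("malformed or non-score XML raises a parse error", {
  bad <- writeRawXML(c("<score-partwise><part id='P1'>"))
  expect_error(parseScore(bad), "malformed XML")
  notscore <- writeRawXML(c("<?xml version=\"1.0\"?>", "<foo><bar/></foo>"))
  expect_error(parseScore(notscore), "not a MusicXML score")
  expect_error(parseScore(tempfile()), "does not exist")
})

test_that("voice extraction takes per-event extrema and keeps repeats", {
  ev <- new("ScoreEvents", onsets = c(0, 1, 2), divisions = 1L,
            pitches = list(c(60L, 64L, 67L), c(59L, 62L, 67L), c(60L, 64L)))
  expect_equal(pitches(extractVoice(ev, "melody")), c(67L, 67L, 64L))
  expect_equal(pitches(extractVoice(ev, "bass")), c(60L, 59L, 60L))
  mono <- new("ScoreEvents", onsets = 0:1, divisions = 1L,
              pitches = list(62L, 64L))
  expect_equal(pitches(extractVoice(mono, "melody")),
               pitches(extractVoice(mono, "bass")))
  empty <- new("ScoreEvents", onsets = numeric(0), pitches = list(),
               divisions = 1L)
  expect_error(extractVoice(empty, "melody", pieceId = "p9"), "p9")
})

test_that("corpus loading groups by unit and propagates labels", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "a.xml"); fb <- file.path(dir, "b.xml")
  writeMusicXMLFixture(c(67L, 69L, 71L), c(48L, 50L, 52L), fa)
  writeMusicXMLFixture(c(72L, 70L), c(55L, 53L), fb)
  man <- data.frame(path = c(fa, fb), piece_id = c("a", "b"),
                    unit_id = "No1", mode = "minor",
                    stringsAsFactors = FALSE)
  corpus <- loadCorpus(man, quiet = TRUE)
  expect_equal(length(linesFor(corpus, unit = "No1", voice = "melody")), 2L)
  expect_equal(length(linesFor(corpus, unit = "No1", voice = "bass")), 2L)
  expect_true(all(vapply(corpusLines(corpus), modeOf, character(1)) ==
                    "minor"))
  # melody >= bass at every event of every piece
  for (u in unitIds(corpus)) {
    mel <- linesFor(corpus, u, "melody"); bas <- linesFor(corpus, u, "bass")
    for (i in seq_along(mel))
      expect_true(all(pitches(mel[[i]]) >= pitches(bas[[i]])))
  }

  man$path[2] <- file.path(dir, "missing.xml")
  expect_error(loadCorpus(man, quiet = TRUE), "missing.xml")
  man$path[2] <- fb; man$mode[2] <- "dorian"
  expect_error(loadCorpus(man, quiet = TRUE), "mode")
})

test_that("unparsable corpus files can be skipped or abort the load", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "ok.xml")
  writeMusicXMLFixture(c(67L, 69L), c(48L, 50L), fa)
  fbad <- file.path(dir, "bad.xml")
  writeLines("<score-partwise><oops>", fbad)
  man <- data.frame(path = c(fa, fbad), piece_id = c("ok", "bad"),
                    unit_id = c("U", "U"), mode = "unknown",
                    stringsAsFactors = FALSE)
  expect_error(loadCorpus(man, quiet = TRUE), "malformed XML")
  expect_warning(corpus <- loadCorpus(man, onParseError = "skip",
                                      quiet = TRUE), "skipping")
  expect_equal(length(corpus), 1L)
})
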