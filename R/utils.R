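`%||%` <- function(a, b) if (is.null(a)) b else a

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
.lcm2 <- function(a, b) a %/% .gcd(a, b) * b

# FNV-1a over a character scalar; used to stamp outputs with a config hash.
# The 32-bit modular multiply is done on 16-bit halves to stay inside the
# exactly-representable double range.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) +
      (if (h >= 2147483648) 2147483648 else 0)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

.configHash <- function(cfg) {
  .fnv1a(paste(deparse(cfg, control = "all"), collapse = "\n"))
}

# Serialise an interval pattern as "(a,b,...)"; the empty context is "()".
patternKey <- function(offsets) {
  if (length(offsets) == 0L) return("()")
  paste0("(", paste(offsets, collapse = ","), ")")
}

# Row-wise key matrix -> "(a,b)" strings without per-row apply().
.patternKeys <- function(mat) {
  if (ncol(mat) == 0L) return(rep("()", nrow(mat)))
  body <- mat[, 1]
  if (ncol(mat) > 1L)
    for (j in 2:ncol(mat)) body <- paste(body, mat[, j], sep = ",")
  paste0("(", body, ")")
}

# One Dirichlet(alpha) draw per row, k categories.
.rdirichlet <- function(nrow, k, alpha) {
  g <- matrix(stats::rgamma(nrow * k, shape = alpha), nrow = nrow)
  g / rowSums(g)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf <- function(...) message(sprintf(...))

#' Construct a VoiceLine
#'
#' @param pitches integer vector of MIDI pitches (middle C = 60).
#' @param pieceId,unitId identifying labels.
#' @param voice `"melody"` or `"bass"`.
#' @param mode `"major"`, `"minor"` or `"unknown"`.
#' @return A [VoiceLine-class] object.
#' @export
#' @examples
#' VoiceLine(c(60L, 62L, 64L), pieceId = "ex", voice = "melody")
VoiceLine <- function(pitches, pieceId = "", unitId = "", voice = "melody",
                      mode = "unknown") {
  new("VoiceLine", pieceId = as.character(pieceId),
      unitId = as.character(unitId), voice = match.arg(voice, .VOICES),
      mode = match.arg(mode, .MODES), pitches = as.integer(pitches))
}

#' Transpose a voice line by a constant number of semitones
#'
#' @param line a [VoiceLine-class].
#' @param semitones integer shift applied to every pitch.
#' @return The transposed [VoiceLine-class].
#' @export
transposeLine <- function(line, semitones) {
  stopifnot(is(line, "VoiceLine"))
  new("VoiceLine", pieceId = line@pieceId, unitId = line@unitId,
      voice = line@voice, mode = line@mode,
      pitches = line@pitches + as.integer(semitones))
}
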