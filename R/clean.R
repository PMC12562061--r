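#' Transcript cleaning configuration
#'
#' Interjections are matched case-insensitively at word boundaries (so "um"
#' is removed but "summer" is untouched); symbol characters are removed
#' wherever they occur. The defaults are the fillers and transcription
#' symbols typical of clinical speech transcripts.
#'
#' @param interjections character vector of filler words to delete.
#' @param strip_symbols character vector of single symbols to delete.
#' @return a `cleaning_config` list.
#' @export
cleaning_config <- function(interjections = c("mhh", "umm", "um"),
                            strip_symbols = c("<", ">", "&", "+")) {
  stopifnot(is.character(interjections), is.character(strip_symbols))
  structure(list(interjections = interjections, strip_symbols = strip_symbols),
            class = "cleaning_config")
}

#' Clean a raw speech transcript
#'
#' Removes configured interjections (word-boundary, case-insensitive) and
#' transcription symbols, then collapses runs of whitespace to single spaces
#' and trims the ends. Idempotent: cleaning twice equals cleaning once.
#'
#' @param raw transcript text (character vector; cleaned element-wise).
#' @param config a [cleaning_config()].
#' @return cleaned text, same length as `raw`; may contain empty strings.
#' @export
clean_transcript <- function(raw, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  out <- raw
  if (length(config$interjections) > 0L) {
    pat <- paste0("(?i)\\b(", paste(config$interjections, collapse = "|"), ")\\b")
    out <- gsub(pat, " ", out, perl = TRUE)
  }
  for (sym in config$strip_symbols) {
    out <- gsub(sym, " ", out, fixed = TRUE)
  }
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Segment a cleaned transcript into independent speech units
#'
#' Splits on terminal punctuation (`.`, `?`, `!`) and on newlines, which
#' stand in for dialogue boundaries. Fragments and phrase-only units (an
#' isolated noun phrase, a stray prepositional phrase) are kept as
#' independent units rather than merged into neighbouring sentences, matching
#' how connected-speech transcripts treat incomplete utterances.
#'
#' @param raw cleaned transcript text (length-1 character).
#' @return character vector of utterance strings, in order; terminal
#'   punctuation is retained with its unit.
#' @export
segment_utterances <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw))) return(character(0))
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  units <- unlist(lapply(lines, function(line) {
    strsplit(line, "(?<=[.?!])\\s+", perl = TRUE)[[1]]
  }), use.names = FALSE)
  units <- trimws(units)
  units[nzchar(units)]
}
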