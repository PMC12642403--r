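#' Time-aligned phoneme/word event table
#'
#' An event table holds one row per phoneme token of a transcribed speech
#' stream, as produced by forced alignment: onset time in seconds, the word
#' the phoneme belongs to, the phoneme symbol, and a flag marking
#' word-initial phonemes. Onsets must be strictly increasing and lie within
#' the stated total duration.
#'
#' @param onset numeric vector of onset times (seconds), strictly
#'   increasing.
#' @param word character vector of word labels (the carrier word of each
#'   phoneme).
#' @param phoneme character vector of phoneme symbols.
#' @param word_initial logical vector; `TRUE` for the first phoneme of each
#'   word.
#' @param duration total duration in seconds; defaults to the last onset
#'   plus 0.1 s.
#' @return An object of class `"event_table"` (a data frame) with the
#'   duration in `attr(, "duration")`.
#' @export
event_table <- function(onset, word, phoneme, word_initial,
                        duration = NULL) {
  onset <- as.numeric(onset)
  n <- length(onset)
  if (is.null(duration))
    duration <- if (n) onset[n] + 0.1 else 0
  if (n) {
    if (any(diff(onset) <= 0))
      stop("event onsets must be strictly increasing")
    if (onset[1L] < 0) stop("event onsets must be nonnegative")
    if (onset[n] >= duration)
      stop("all onsets must lie before the total duration")
  }
  word <- as.character(word); phoneme <- as.character(phoneme)
  word_initial <- as.logical(word_initial)
  if (length(word) != n || length(phoneme) != n || length(word_initial) != n)
    stop("all event columns must have the same length")
  if (n) {
    starts <- which(word_initial)
    if (length(starts) == 0L || starts[1L] != 1L)
      stop("the first event must be word-initial")
    ## within a word run, only the first phoneme may be flagged
    run_id <- cumsum(word_initial)
    first_of_run <- !duplicated(run_id)
    if (!identical(unname(word_initial), unname(first_of_run)))
      stop("exactly the first phoneme of each word must be word-initial")
  }
  out <- data.frame(onset = onset, word = word, phoneme = phoneme,
                    word_initial = word_initial, stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  attr(out, "duration") <- duration
  out
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table: ", nrow(x), " phoneme events, ",
      sum(x$word_initial), " words, duration ",
      format(attr(x, "duration")), " s\n", sep = "")
  print.data.frame(utils::head(x, 8L))
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Read / write event tables as tab-separated text
#'
#' Format: header `onset_s  word  phoneme  word_initial` (0/1 flag), one
#' row per phoneme event, plus the total duration recorded in a
#' `# duration_s:` comment line. Onsets are validated as strictly
#' increasing on read, with the offending line reported.
#'
#' @param path file path.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  dur <- NA_real_
  cm <- grep("^# *duration_s:", lines)
  if (length(cm))
    dur <- as.numeric(sub("^# *duration_s: *", "", lines[cm[1L]]))
  body_idx <- which(!startsWith(lines, "#"))
  body <- lines[body_idx]
  if (length(body) == 0L) stop("event file has no header")
  hdr <- strsplit(body[1L], "\t")[[1L]]
  need <- c("onset_s", "word", "phoneme", "word_initial")
  if (!identical(hdr, need))
    stop("event file header must be: ", paste(need, collapse = ", "))
  if (length(body) == 1L)
    return(event_table(numeric(0), character(0), character(0), logical(0),
                       duration = if (is.na(dur)) 0 else dur))
  d <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  bad <- which(diff(d$onset_s) <= 0)
  if (length(bad))
    stop("event onsets not strictly increasing at line ",
         body_idx[bad[1L] + 2L], " of ", path)
  event_table(d$onset_s, d$word, d$phoneme, d$word_initial == 1,
              duration = if (is.na(dur)) NULL else dur)
}

#' @rdname read_events
#' @param events an `event_table`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s: %.17g", attr(events, "duration")), con)
  d <- data.frame(onset_s = sprintf("%.17g", events$onset),
                  word = events$word, phoneme = events$phoneme,
                  word_initial = as.integer(events$word_initial),
                  stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split an event table into per-word phoneme sequences
#'
#' @param events an `event_table`.
#' @return A list with one element per word token: `word`, integer event
#'   row indices, and the phoneme sequence.
#' @keywords internal
events_by_word <- function(events) {
  if (nrow(events) == 0L) return(list())
  run_id <- cumsum(events$word_initial)
  lapply(split(seq_len(nrow(events)), run_id), function(ix) {
    list(word = events$word[ix[1L]], rows = ix,
         phonemes = events$phoneme[ix])
  })
}
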