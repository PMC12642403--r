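#' Sampled predictor time series
#'
#' A predictor track is a uniformly sampled real-valued time series aligned
#' to a response: either an impulse track (zero everywhere except at event
#' samples, where the impulse carries a feature value) or a continuous
#' track (e.g. an acoustic band envelope).
#'
#' @param values numeric sample vector.
#' @param fs sampling rate in Hz (> 0).
#' @param name track name.
#' @param kind `"impulse"` or `"continuous"`.
#' @return An object of class `"predictor_track"`.
#' @export
predictor_track <- function(values, fs, name = "track",
                            kind = c("impulse", "continuous")) {
  kind <- match.arg(kind)
  if (fs <= 0) stop("`fs` must be > 0")
  structure(list(name = name, fs = fs, values = as.numeric(values),
                 kind = kind),
            class = "predictor_track")
}

#' @export
print.predictor_track <- function(x, ...) {
  cat("Predictor track '", x$name, "': ", length(x$values), " samples @ ",
      x$fs, " Hz (", x$kind, ")\n", sep = "")
  invisible(x)
}

## nearest sample for an onset time; ties between two samples resolve to
## the earlier one
event_sample <- function(onset, fs) {
  as.integer(ceiling(onset * fs - 0.5)) + 1L  # 1-based
}

track_length <- function(duration, fs) max(1L, as.integer(ceiling(duration * fs)))

#' Word-onset and phoneme-onset impulse tracks
#'
#' Places a unit impulse at the sample nearest to each event onset. Word
#' onsets go into the word track; all other phoneme onsets go into the
#' phoneme track, so the two tracks never mark the same event (avoiding
#' collinearity between them). Ties between two samples round to the
#' earlier sample; impulses that collide on one sample are summed.
#'
#' @param events an [event_table()].
#' @param fs sampling rate in Hz.
#' @return A list with `word` and `phoneme` predictor tracks of equal
#'   length `ceiling(duration * fs)`.
#' @export
onset_tracks <- function(events, fs) {
  stopifnot(inherits(events, "event_table"))
  if (fs <= 0) stop("`fs` must be > 0")
  n <- track_length(attr(events, "duration"), fs)
  wtrack <- numeric(n)
  ptrack <- numeric(n)
  if (nrow(events)) {
    ix <- pmin(pmax(event_sample(events$onset, fs), 1L), n)
    for (k in seq_along(ix)) {
      if (events$word_initial[k]) wtrack[ix[k]] <- wtrack[ix[k]] + 1
      else ptrack[ix[k]] <- ptrack[ix[k]] + 1
    }
  }
  list(word = predictor_track(wtrack, fs, "word_onset", "impulse"),
       phoneme = predictor_track(ptrack, fs, "phoneme_onset", "impulse"))
}

#' Impulse track scaled by per-event feature values
#'
#' Turns a feature sequence (e.g. surprisal per phoneme event) into a
#' sampled predictor: an impulse of magnitude equal to the feature value at
#' the sample nearest each covered event's onset, zero elsewhere.
#' Colliding impulses are summed.
#'
#' @param events an [event_table()].
#' @param values numeric vector of feature values, or a
#'   `feature_sequence` column; must cover `rows`.
#' @param fs sampling rate in Hz.
#' @param rows integer event rows the values correspond to (default: all).
#' @param name track name.
#' @export
feature_track <- function(events, values, fs, rows = seq_len(nrow(events)),
                          name = "feature") {
  stopifnot(inherits(events, "event_table"))
  values <- as.numeric(values)
  if (length(values) != length(rows))
    stop("`values` length (", length(values),
         ") must match the number of covered events (", length(rows), ")")
  n <- track_length(attr(events, "duration"), fs)
  tr <- numeric(n)
  if (length(rows)) {
    ix <- pmin(pmax(event_sample(events$onset[rows], fs), 1L), n)
    for (k in seq_along(ix)) tr[ix[k]] <- tr[ix[k]] + values[k]
  }
  predictor_track(tr, fs, name, "impulse")
}

#' Standardize a track or response to zero mean and unit mean-absolute value
#'
#' Centers the input and divides by the mean absolute deviation, the
#' normalization applied to every predictor and response before mTRF
#' estimation (so that one boosting step size is meaningful across
#' predictors).
#'
#' @param x numeric vector.
#' @return A list with `values` (standardized), `center` and `scale`.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  center <- mean(x)
  scale <- mean(abs(x - center))
  if (scale <= 0)
    stop("degenerate input: constant series cannot be standardized")
  list(values = (x - center) / scale, center = center, scale = scale)
}

#' Read / write a set of predictor tracks as delimited text
#'
#' Serializes a named list of predictor tracks into a single tab-separated
#' text container: per-track metadata (`name`, `fs`, `kind`) in comment
#' lines followed by one column of samples per track. All tracks must share
#' length.
#'
#' @param tracks named list of `predictor_track`s.
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(is.list(tracks), length(tracks) > 0L,
            all(vapply(tracks, inherits, TRUE, "predictor_track")))
  lens <- vapply(tracks, function(t) length(t$values), 0L)
  if (length(unique(lens)) != 1L)
    stop("all tracks in a container must share length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name: %s",
                     paste(vapply(tracks, `[[`, "", "name"), collapse = "\t")),
             con)
  writeLines(sprintf("# fs: %s",
                     paste(vapply(tracks, function(t) format(t$fs), ""),
                           collapse = "\t")), con)
  writeLines(sprintf("# kind: %s",
                     paste(vapply(tracks, `[[`, "", "kind"), collapse = "\t")),
             con)
  m <- vapply(tracks, `[[`, numeric(lens[1L]), "values")
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  lines <- readLines(path, n = 3L)
  meta <- lapply(c("name", "fs", "kind"), function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("track container missing '# ", key, ":' line")
    strsplit(sub(paste0("^# ", key, ": "), "", ln[1L]), "\t")[[1L]]
  })
  m <- as.matrix(utils::read.delim(path, comment.char = "#",
                                   header = FALSE))
  out <- lapply(seq_along(meta[[1L]]), function(j)
    predictor_track(m[, j], as.numeric(meta[[2L]][j]), meta[[1L]][j],
                    meta[[3L]][j]))
  names(out) <- meta[[1L]]
  out
}
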