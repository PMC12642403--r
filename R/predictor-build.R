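#' Registry of linguistic predictor features
#'
#' The speech language features available to TRF models: surprisal,
#' cohort entropy and phoneme entropy at the sublexical, lexical and
#' sentence context levels (cohort entropy is not defined for sublexical
#' context — there is no word cohort without a word onset), plus the
#' word/phoneme onset impulse predictors.
#'
#' @return Data frame with columns `name`, `level`, `measure`, `defined`.
#' @export
feature_registry <- function() {
  levels_ <- c("sublexical", "lexical", "sentence")
  measures <- c("surprisal", "cohort_entropy", "phoneme_entropy")
  grid <- expand.grid(level = levels_, measure = measures,
                      stringsAsFactors = FALSE)
  grid$name <- paste(grid$level, grid$measure, sep = "_")
  grid$defined <- !(grid$level == "sublexical" &
                      grid$measure == "cohort_entropy")
  onsets <- data.frame(level = "onset", measure = c("word", "phoneme"),
                       name = c("word_onset", "phoneme_onset"),
                       defined = TRUE)
  rbind(onsets, grid[, c("level", "measure", "name", "defined")])
}

#' Build a predictor set from an event table
#'
#' Constructs the requested predictor tracks at the analysis sampling
#' rate: word/phoneme onset impulses and impulse tracks carrying
#' surprisal, phoneme entropy and cohort entropy under the sublexical
#' (phoneme n-gram), lexical (frequency-prior cohort) and sentence
#' (word-n-gram-prior cohort) context models. Context models that are
#' needed but not supplied are trained on the event table's own phoneme
#' and word sequences (a self-trained toy stand-in for external training
#' corpora; pass `phoneme_lm` / `word_lm` to use models trained
#' elsewhere, e.g. read from ARPA files).
#'
#' @param events an [event_table()].
#' @param lex a [lexicon()] covering the event words (needed for
#'   lexical/sentence features).
#' @param fs analysis sampling rate (Hz).
#' @param features character vector of feature names from
#'   [feature_registry()].
#' @param phoneme_lm optional `ngram_model` over phonemes.
#' @param word_lm optional `ngram_model` over words.
#' @param order n-gram order for self-trained models (default 5).
#' @param discount absolute discount for self-trained models.
#' @param base log base for surprisal/entropy values.
#' @return Named list of [predictor_track()]s, in the order requested.
#' @export
build_predictors <- function(events, lex = NULL, fs = 100,
                             features = c("word_onset", "phoneme_onset",
                                          "sublexical_surprisal"),
                             phoneme_lm = NULL, word_lm = NULL,
                             order = 5L, discount = 0.1,
                             base = exp(1)) {
  stopifnot(inherits(events, "event_table"))
  reg <- feature_registry()
  unknown <- setdiff(features, reg$name)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  undef <- intersect(features, reg$name[!reg$defined])
  if (length(undef))
    stop(paste(undef, collapse = ", "),
         " is not defined (cohort entropy requires a word cohort)")

  out <- list()
  onsets <- NULL
  need_onsets <- any(c("word_onset", "phoneme_onset") %in% features)
  if (need_onsets) onsets <- onset_tracks(events, fs)

  need_sub <- any(startsWith(features, "sublexical_"))
  need_lex <- any(startsWith(features, "lexical_"))
  need_sen <- any(startsWith(features, "sentence_"))
  sub_feats <- lex_feats <- sen_feats <- NULL
  if (need_sub) {
    if (is.null(phoneme_lm)) {
      max_ord <- min(order, nrow(events))
      phoneme_lm <- train_ngram(list(events$phoneme), max_ord,
                                discount = discount, pad = TRUE)
    }
    sub_feats <- sublexical_features(events, phoneme_lm, base = base)
  }
  if (need_lex || need_sen) {
    if (is.null(lex))
      stop("lexical/sentence features require a lexicon")
    if (need_lex)
      lex_feats <- cohort_features(events, lex, "frequency", base = base)
    if (need_sen) {
      if (is.null(word_lm)) {
        tokens <- events$word[events$word_initial]
        word_lm <- train_ngram(list(tokens), min(order, length(tokens)),
                               discount = discount, pad = TRUE)
      }
      sen_feats <- cohort_features(events, lex, "sentence",
                                   word_lm = word_lm, base = base)
    }
  }
  for (f in features) {
    out[[f]] <- switch(
      f,
      word_onset = onsets$word,
      phoneme_onset = onsets$phoneme,
      {
        fr <- if (startsWith(f, "sublexical_")) sub_feats
              else if (startsWith(f, "lexical_")) lex_feats
              else sen_feats
        col <- sub("^(sublexical|lexical|sentence)_", "", f)
        col <- if (col == "surprisal") "surprisal" else col
        feature_track(events, fr[[col]], fs, name = f)
      })
  }
  out
}
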