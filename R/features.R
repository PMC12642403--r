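feature_sequence <- function(rows, surprisal, phoneme_entropy,
                             cohort_entropy = NULL, oov = NULL,
                             base = exp(1), level = "sublexical") {
  n <- length(surprisal)
  out <- data.frame(event = rows, surprisal = surprisal,
                    phoneme_entropy = phoneme_entropy)
  out$cohort_entropy <- if (is.null(cohort_entropy)) NA_real_ else cohort_entropy
  out$oov <- if (is.null(oov)) rep(FALSE, n) else oov
  stopifnot(all(out$surprisal >= -1e-12, na.rm = TRUE),
            all(out$phoneme_entropy >= -1e-12, na.rm = TRUE))
  class(out) <- c("feature_sequence", "data.frame")
  attr(out, "base") <- base
  attr(out, "level") <- level
  out
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat("Feature sequence (", attr(x, "level"), " context, log base ",
      format(attr(x, "base")), "): ", nrow(x), " events\n", sep = "")
  print.data.frame(utils::head(x, 8L))
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' Sublexical context features: phoneme surprisal and entropy
#'
#' Computes, for every phoneme event, its surprisal given the preceding
#' `order - 1` phonemes under a phoneme n-gram model,
#' \eqn{I = -\log p(\mathrm{phoneme}_k \mid \mathrm{context})}, and the
#' entropy of the predicted next-phoneme distribution given the context
#' that ends at the current phoneme (the average expected surprisal of the
#' following phoneme). With the default 5-gram model the surprisal context
#' is the previous four phonemes and the entropy context the previous
#' three plus the current one.
#'
#' By default the context crosses word boundaries — it is simply the
#' phonemes heard — with the model's padding symbol filling the context at
#' the start of the utterance. Set `cross_word_boundaries = FALSE` to reset
#' the context at each word onset instead.
#'
#' @param events an [event_table()].
#' @param model an `ngram_model` over phonemes (see [train_ngram()]).
#' @param base logarithm base for surprisal/entropy (default natural log).
#' @param cross_word_boundaries logical, see Details.
#' @return A `feature_sequence` data frame with one row per phoneme event:
#'   `surprisal`, `phoneme_entropy` (`cohort_entropy` is undefined at the
#'   sublexical level and filled with `NA`).
#' @export
sublexical_features <- function(events, model, base = exp(1),
                                cross_word_boundaries = TRUE) {
  stopifnot(inherits(events, "event_table"), inherits(model, "ngram_model"))
  n <- nrow(events)
  unknown <- setdiff(unique(events$phoneme), model$vocabulary)
  if (length(unknown))
    stop("phoneme symbols not in model vocabulary: ",
         paste(unknown, collapse = ", "))
  ctx_len <- model$order - 1L
  pad <- model$pad_symbol
  surprisal <- numeric(n)
  entropy <- numeric(n)
  history <- if (!is.null(pad)) rep(pad, ctx_len) else character(0)
  for (k in seq_len(n)) {
    if (!cross_word_boundaries && events$word_initial[k])
      history <- if (!is.null(pad)) rep(pad, ctx_len) else character(0)
    ctx <- tail(history, ctx_len)
    ph <- events$phoneme[k]
    p <- ngram_prob(model, ph, ctx)
    if (p <= 0)
      stop("infinite surprisal: p(", ph, " | ",
           paste(ctx, collapse = " "), ") = 0 at event ", k)
    surprisal[k] <- -log(p, base = base)
    dist_ctx <- tail(c(ctx, ph), ctx_len)
    entropy[k] <- shannon_entropy(ngram_dist(model, dist_ctx), base = base)
    history <- c(history, ph)
  }
  feature_sequence(seq_len(n), surprisal, entropy, base = base,
                   level = "sublexical")
}

#' Lexical and sentence context features from the cohort model
#'
#' Runs the incremental cohort model over every word of an event table and
#' extracts, per phoneme event: phoneme surprisal (from the probability of
#' all word completions consistent with the phoneme), phoneme entropy (over
#' the next-phoneme distribution implied by the surviving cohort), and
#' cohort entropy (over the candidate-word distribution). The cohort resets
#' at each word onset with the selected prior: word frequency for the
#' lexical context model, or the word's probability under a word n-gram
#' given the preceding four words for the sentence context model.
#'
#' @param events an [event_table()]; every event word must be in the
#'   lexicon.
#' @param lexicon a [lexicon()].
#' @param prior_mode `"frequency"` or `"sentence"`.
#' @param word_lm an `ngram_model` over words; required for
#'   `prior_mode = "sentence"`.
#' @param base logarithm base (default natural log).
#' @return A `feature_sequence` data frame with columns `surprisal`,
#'   `phoneme_entropy`, `cohort_entropy`, and an `oov` flag marking events
#'   handled by the out-of-cohort fallback.
#' @export
cohort_features <- function(events, lexicon,
                            prior_mode = c("frequency", "sentence"),
                            word_lm = NULL, base = exp(1)) {
  stopifnot(inherits(events, "event_table"), inherits(lexicon, "lexicon"))
  prior_mode <- match.arg(prior_mode)
  if (prior_mode == "sentence" && !inherits(word_lm, "ngram_model"))
    stop("`prior_mode = \"sentence\"` requires a word n-gram model")
  words <- events_by_word(events)
  missing <- setdiff(unique(vapply(words, `[[`, "", "word")), lexicon$word)
  if (length(missing))
    stop("word(s) missing from lexicon: ", paste(missing, collapse = ", "))
  n <- nrow(events)
  surprisal <- entropy <- centropy <- numeric(n)
  oov <- logical(n)
  word_history <- character(0)
  for (w in words) {
    prior <- if (prior_mode == "frequency") NULL else {
      ctx <- tail(word_history, word_lm$order - 1L)
      vapply(lexicon$word, function(v) ngram_prob(word_lm, v, ctx), 0)
    }
    state <- cohort_init(lexicon, prior)
    for (k in w$rows) {
      up <- cohort_update(state, events$phoneme[k])
      state <- up$state
      if (up$p_phoneme <= 0)
        stop("infinite surprisal at event ", k)
      surprisal[k] <- -log(up$p_phoneme, base = base)
      entropy[k] <- shannon_entropy(cohort_next_phoneme_dist(state),
                                    base = base)
      centropy[k] <- cohort_entropy(state, base = base)
      oov[k] <- up$oov
    }
    word_history <- c(word_history, w$word)
  }
  feature_sequence(seq_len(n), surprisal, entropy, centropy, oov,
                   base = base,
                   level = if (prior_mode == "frequency") "lexical"
                           else "sentence")
}
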