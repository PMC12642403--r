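#' Incremental cohort model of spoken-word recognition
#'
#' The cohort model tracks a probability distribution over candidate words
#' while the phonemes of a word are heard one by one. `cohort_init()`
#' starts a word with a prior over the whole lexicon (word frequency for
#' the lexical context model, or a sentence-level n-gram prior for the
#' sentence context model). `cohort_update()` consumes one phoneme: every
#' candidate whose transcription is inconsistent with the phonemes heard so
#' far is set to zero and the distribution is renormalized. The probability
#' assigned to the incoming phoneme is the total prior mass of the
#' candidates that continue with it (the probability of every possible word
#' completion), which is what feeds phoneme surprisal.
#'
#' If a phoneme eliminates every candidate (out-of-cohort input, e.g. a
#' noisy alignment), the state degrades to a flagged fallback: the
#' next-phoneme distribution is uniform over the inventory for the rest of
#' the word and the cohort entropy is zero.
#'
#' @param lexicon a [lexicon()].
#' @param prior numeric vector of nonnegative word weights, one per lexicon
#'   word (need not be normalized); `NULL` means word frequency.
#' @return `cohort_init()`: an object of class `"cohort_state"` with
#'   normalized candidate probabilities. `cohort_update()`: a list with
#'   elements `state` (the updated `cohort_state`), `p_phoneme`, and `oov`
#'   (flag: the fallback was in effect for this phoneme).
#' @examples
#' lex <- lexicon(c("cat", "cap", "dog"),
#'                list(c("K", "AE", "T"), c("K", "AE", "P"),
#'                     c("D", "AO", "G")), c(2, 1, 1))
#' st <- cohort_init(lex)
#' up <- cohort_update(st, "K")
#' up$p_phoneme         # 0.75
#' up$state$probs       # cat 2/3, cap 1/3
#' @export
cohort_init <- function(lexicon, prior = NULL) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (is.null(prior)) prior <- lexicon$frequency
  prior <- as.numeric(prior)
  if (length(prior) != nrow(lexicon))
    stop("`prior` must have one weight per lexicon word")
  if (any(prior < 0) || any(!is.finite(prior)))
    stop("`prior` must be nonnegative and finite")
  tot <- sum(prior)
  if (tot == 0) stop("`prior` must not be all zero")
  keep <- prior > 0
  structure(
    list(words = lexicon$word[keep],
         transcriptions = lexicon$phonemes[keep],
         probs = prior[keep] / tot,
         consumed = 0L,
         oov = FALSE,
         inventory = phoneme_inventory(lexicon)),
    class = "cohort_state")
}

#' @rdname cohort_init
#' @param state a `cohort_state`.
#' @param phoneme the phoneme symbol heard next.
#' @export
cohort_update <- function(state, phoneme) {
  stopifnot(inherits(state, "cohort_state"))
  if (state$oov) {
    state$consumed <- state$consumed + 1L
    return(list(state = state,
                p_phoneme = 1 / length(state$inventory), oov = TRUE))
  }
  if (length(state$words) == 0L) stop("cohort state is empty")
  pos <- state$consumed + 1L
  nxt <- vapply(state$transcriptions, function(tr)
    if (length(tr) >= pos) tr[pos] else NA_character_, "")
  match <- !is.na(nxt) & nxt == phoneme
  p <- sum(state$probs[match])
  if (p <= 0) {
    state$words <- character(0)
    state$transcriptions <- list()
    state$probs <- numeric(0)
    state$oov <- TRUE
    state$consumed <- state$consumed + 1L
    return(list(state = state,
                p_phoneme = 1 / length(state$inventory), oov = TRUE))
  }
  state$words <- state$words[match]
  state$transcriptions <- state$transcriptions[match]
  state$probs <- state$probs[match] / p
  state$consumed <- state$consumed + 1L
  list(state = state, p_phoneme = p, oov = FALSE)
}

#' Next-phoneme distribution implied by a cohort state
#'
#' Aggregates candidate mass by upcoming phoneme and normalizes over the
#' candidates that still have one (words whose transcription is already
#' complete contribute no continuation). Under the out-of-cohort fallback
#' the distribution is uniform over the inventory.
#'
#' @param state a `cohort_state`.
#' @return Named probability vector over the phoneme inventory (all zeros
#'   if no candidate continues).
#' @export
cohort_next_phoneme_dist <- function(state) {
  stopifnot(inherits(state, "cohort_state"))
  q <- stats::setNames(numeric(length(state$inventory)), state$inventory)
  if (state$oov) {
    q[] <- 1 / length(q)
    return(q)
  }
  pos <- state$consumed + 1L
  for (i in seq_along(state$words)) {
    tr <- state$transcriptions[[i]]
    if (length(tr) >= pos) q[[tr[pos]]] <- q[[tr[pos]]] + state$probs[i]
  }
  tot <- sum(q)
  if (tot > 0) q <- q / tot
  q
}

#' Word (cohort) entropy of a cohort state
#'
#' Entropy over the candidate-word distribution consistent with the
#' phonemes heard so far; zero for a singleton cohort and, by convention,
#' zero under the out-of-cohort fallback.
#'
#' @param state a `cohort_state`.
#' @param base logarithm base.
#' @export
cohort_entropy <- function(state, base = exp(1)) {
  stopifnot(inherits(state, "cohort_state"))
  if (state$oov || length(state$probs) == 0L) return(0)
  shannon_entropy(state$probs, base = base)
}

#' @export
print.cohort_state <- function(x, ...) {
  if (x$oov) {
    cat("Cohort state: out-of-cohort fallback after", x$consumed,
        "phonemes\n")
  } else {
    cat("Cohort state:", length(x$words), "candidates after", x$consumed,
        "phonemes\n")
    k <- order(x$probs, decreasing = TRUE)[seq_len(min(5L, length(x$probs)))]
    cat(paste(sprintf("  %s %.4f", x$words[k], x$probs[k]), collapse = "\n"),
        "\n")
  }
  invisible(x)
}
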