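#' Pronunciation lexicon
#'
#' A lexicon maps word labels to phoneme transcriptions and corpus frequency
#' counts, and carries the phoneme inventory over which next-phoneme
#' distributions are defined. It backs the lexical and sentence context
#' (cohort) models.
#'
#' @param words character vector of unique word labels.
#' @param phonemes list of character vectors, one transcription per word.
#' @param frequencies numeric vector of nonnegative counts; at least one
#'   must be positive.
#' @param inventory optional character vector of phoneme symbols; defaults
#'   to the sorted union of all transcription symbols. Every transcription
#'   phoneme must be contained in it.
#' @return An object of class `"lexicon"`: a data frame with columns
#'   `word`, `frequency` and list-column `phonemes`, with the inventory in
#'   `attr(, "inventory")`.
#' @examples
#' lex <- lexicon(c("cat", "cap", "dog"),
#'                list(c("K", "AE", "T"), c("K", "AE", "P"),
#'                     c("D", "AO", "G")),
#'                c(2, 1, 1))
#' phoneme_inventory(lex)
#' @export
lexicon <- function(words, phonemes, frequencies, inventory = NULL) {
  words <- as.character(words)
  if (anyDuplicated(words))
    stop("word labels must be unique (one transcription per word)")
  if (!is.list(phonemes) || length(phonemes) != length(words))
    stop("`phonemes` must be a list of transcriptions, one per word")
  phonemes <- lapply(phonemes, as.character)
  if (any(lengths(phonemes) == 0L))
    stop("every word needs a non-empty transcription")
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != length(words) || any(frequencies < 0) ||
      any(!is.finite(frequencies)))
    stop("`frequencies` must be nonnegative finite counts, one per word")
  if (!any(frequencies > 0))
    stop("at least one word must have frequency > 0")
  used <- sort(unique(unlist(phonemes)))
  if (is.null(inventory)) {
    inventory <- used
  } else {
    inventory <- as.character(inventory)
    missing <- setdiff(used, inventory)
    if (length(missing))
      stop("transcription phonemes not in inventory: ",
           paste(missing, collapse = ", "))
  }
  out <- data.frame(word = words, frequency = frequencies,
                    stringsAsFactors = FALSE)
  out$phonemes <- phonemes
  class(out) <- c("lexicon", "data.frame")
  attr(out, "inventory") <- inventory
  out
}

#' @rdname lexicon
#' @param x a `lexicon`.
#' @export
phoneme_inventory <- function(x) {
  stopifnot(inherits(x, "lexicon"))
  attr(x, "inventory")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Lexicon: ", nrow(x), " words, inventory of ",
      length(attr(x, "inventory")), " phonemes\n", sep = "")
  show <- utils::head(x, 6L)
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %-12s %8g  /%s/\n", show$word[i], show$frequency[i],
                paste(show$phonemes[[i]], collapse = " ")))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read / write a lexicon as tab-separated text
#'
#' The on-disk format is `word<TAB>frequency<TAB>phonemes`, phonemes
#' space-separated, with a header line. The inventory is reconstructed from
#' the transcriptions on read.
#'
#' @param path file path.
#' @export
read_lexicon <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("word", "frequency", "phonemes")
  if (!all(need %in% names(d)))
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  lexicon(d$word, strsplit(d$phonemes, " +"), d$frequency)
}

#' @rdname read_lexicon
#' @param lex a `lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  d <- data.frame(word = lex$word, frequency = lex$frequency,
                  phonemes = vapply(lex$phonemes, paste, "", collapse = " "),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
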