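#' Read and write n-gram models in ARPA format
#'
#' The ARPA text format stores, per n-gram order, log10 probabilities of
#' seen n-grams and log10 backoff weights of contexts, which is exactly the
#' internal representation of [train_ngram()] models, so round-trips are
#' lossless to printed precision. A weight of `-99` is used, conventionally,
#' to encode a true zero (`log10(0)`); entries that exist only as contexts
#' of higher-order n-grams are written with probability `-99` as well.
#'
#' @param path file path.
#' @return `read_arpa()` returns an `ngram_model`; its `discount` is `NA`
#'   since the file does not record how it was estimated.
#' @export
read_arpa <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  if (!any(lines == "\\data\\"))
    stop("ARPA parse error: missing \\data\\ header")
  i_data <- which(lines == "\\data\\")[1L]
  counts <- integer(0)
  i <- i_data + 1L
  while (i <= length(lines) && grepl("^ngram ", lines[i])) {
    m <- regmatches(lines[i], regexec("^ngram ([0-9]+)=([0-9]+)$", lines[i]))[[1L]]
    if (length(m) != 3L)
      stop("ARPA parse error: malformed count line in \\data\\ section: ",
           lines[i])
    counts[as.integer(m[2L])] <- as.integer(m[3L])
    i <- i + 1L
  }
  if (length(counts) == 0L)
    stop("ARPA parse error: no ngram counts in \\data\\ section")
  order <- length(counts)
  model <- structure(
    list(order = order, vocabulary = character(0), discount = NA_real_,
         prob = lapply(seq_len(order), function(k) new.env(hash = TRUE)),
         bow = lapply(seq_len(order), function(k) new.env(hash = TRUE)),
         unk_log10 = -Inf, pad_symbol = NULL),
    class = "ngram_model")
  for (k in seq_len(order)) {
    hdr <- paste0("\\", k, "-grams:")
    i_k <- which(lines == hdr)
    if (length(i_k) != 1L)
      stop("ARPA parse error: missing section ", hdr)
    i <- i_k + 1L
    while (i <= length(lines) && nzchar(lines[i]) &&
           !startsWith(lines[i], "\\")) {
      parts <- strsplit(lines[i], "[ \t]+")[[1L]]
      if (length(parts) < k + 1L)
        stop("ARPA parse error in section ", hdr, ": ", lines[i])
      lp <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(lp))
        stop("ARPA parse error in section ", hdr, ": bad log-probability in ",
             lines[i])
      gram <- paste(parts[2:(k + 1L)], collapse = " ")
      has_bow <- length(parts) == k + 2L
      if (lp <= -98.9) lp <- -Inf
      assign(gram, lp, envir = model$prob[[k]])
      if (has_bow) {
        b <- as.numeric(parts[k + 2L])
        if (b <= -98.9) b <- -Inf
        assign(gram, b, envir = model$bow[[k]])
      }
      i <- i + 1L
    }
  }
  uni <- ls(model$prob[[1L]])
  if ("<unk>" %in% uni) {
    model$unk_log10 <- get("<unk>", envir = model$prob[[1L]])
    rm("<unk>", envir = model$prob[[1L]])
    uni <- setdiff(uni, "<unk>")
  }
  ## tokens present only as contexts (probability written as -99) are not
  ## part of the predictable vocabulary
  real <- vapply(uni, function(w) get(w, envir = model$prob[[1L]]) > -Inf, TRUE)
  model$vocabulary <- sort(uni[real])
  model
}

#' @rdname read_arpa
#' @param model an `ngram_model`.
#' @export
write_arpa <- function(model, path) {
  stopifnot(inherits(model, "ngram_model"))
  fmt <- function(x) ifelse(is.finite(x), sprintf("%.7f", x), "-99")
  sections <- character(0)
  ns <- integer(model$order)
  for (k in seq_len(model$order)) {
    grams <- sort(unique(c(ls(model$prob[[k]]), ls(model$bow[[k]]))))
    if (k == 1L && model$unk_log10 > -Inf) grams <- sort(c(grams, "<unk>"))
    ns[k] <- length(grams)
    body <- vapply(grams, function(g) {
      lp <- if (k == 1L && g == "<unk>") model$unk_log10 else
        get0(g, envir = model$prob[[k]], inherits = FALSE)
      if (is.null(lp)) lp <- -Inf
      b <- get0(g, envir = model$bow[[k]], inherits = FALSE)
      if (is.null(b)) paste(fmt(lp), g, sep = "\t")
      else paste(fmt(lp), g, fmt(b), sep = "\t")
    }, "")
    sections <- c(sections, "", paste0("\\", k, "-grams:"), body)
  }
  header <- c("\\data\\", sprintf("ngram %d=%d", seq_len(model$order), ns))
  writeLines(c(header, sections, "", "\\end\\"), path)
  invisible(path)
}
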