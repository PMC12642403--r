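#' Train a backoff n-gram model
#'
#' Fits a fixed-order n-gram model with interpolated absolute discounting:
#' \deqn{p_k(w \mid c) = \frac{\max(C(cw) - d, 0)}{C(c)} +
#'       \frac{d\,N_{1+}(c)}{C(c)}\; p_{k-1}(w \mid c'),}
#' where \eqn{C} are counts, \eqn{N_{1+}(c)} the number of distinct
#' continuations of context \eqn{c}, \eqn{c'} the context with its first
#' token dropped, and the recursion bottoms out at a uniform distribution
#' over the vocabulary. With `discount = 0` the conditionals for seen
#' contexts are exactly the maximum-likelihood count ratios. The model is
#' stored in backoff (ARPA-style) form: a log10 probability per seen
#' n-gram plus a log10 backoff weight per seen context, so it can be
#' written to and read from standard ARPA files losslessly.
#'
#' Used both for the sublexical context model (a 5-gram over phonemes,
#' trained on phoneme sequences) and the sentence context model (a 5-gram
#' over words).
#'
#' @param corpus a character vector of tokens (one sequence) or a list of
#'   such vectors (multiple independent sequences).
#' @param order model order \eqn{n \ge 1}; conditioning context has
#'   `order - 1` tokens.
#' @param discount absolute discount \eqn{d \in [0, 1)}.
#' @param pad if `TRUE`, each sequence is prefixed with `order - 1` copies
#'   of `pad_symbol`, so that initial tokens have full-length contexts. The
#'   pad symbol appears only in contexts, never as a predicted token.
#' @param pad_symbol the padding symbol.
#' @return An object of class `"ngram_model"`.
#' @examples
#' m <- train_ngram(strsplit("A B A B A C", " ")[[1]], order = 2)
#' ngram_prob(m, "B", "A")  # 2/3
#' @export
train_ngram <- function(corpus, order, discount = 0, pad = FALSE,
                        pad_symbol = "<s>") {
  if (is.character(corpus)) corpus <- list(corpus)
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("`corpus` must be a non-empty token vector or list of them")
  corpus <- lapply(corpus, as.character)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("`corpus` is empty")
  if (order < 1L) stop("`order` must be >= 1")
  if (discount < 0 || discount >= 1) stop("`discount` must be in [0, 1)")
  if (order > max(lengths(corpus)) + 1L)
    stop("`order` (", order, ") exceeds longest sequence length + 1")
  if (any(vapply(corpus, function(s) pad_symbol %in% s, TRUE)))
    stop("corpus must not contain the pad symbol ", pad_symbol)

  vocab <- sort(unique(unlist(corpus)))
  padded <- if (pad && order > 1L) {
    lapply(corpus, function(s) c(rep(pad_symbol, order - 1L), s))
  } else corpus
  n_pad <- if (pad && order > 1L) order - 1L else 0L

  ## k-gram counts, for grams ending at a real (non-pad) token
  counts <- vector("list", order)
  for (k in seq_len(order)) {
    grams <- unlist(lapply(padded, function(s) {
      n <- length(s)
      if (n < k) return(character(0))
      g <- do.call(paste, lapply(seq_len(k), function(j) s[j:(n - k + j)]))
      ## drop grams ending inside the pad prefix
      if (n_pad >= k) g <- g[-seq_len(n_pad - k + 1L)]
      g
    }))
    counts[[k]] <- table_counts(grams)
  }

  model <- structure(
    list(order = as.integer(order), vocabulary = vocab,
         discount = discount,
         prob = lapply(seq_len(order), function(k) new.env(hash = TRUE)),
         bow = lapply(seq_len(order), function(k) new.env(hash = TRUE)),
         unk_log10 = -Inf,
         pad_symbol = if (pad) pad_symbol else NULL),
    class = "ngram_model")

  nv <- length(vocab)
  ## level 1
  tot <- sum(counts[[1L]]$count)
  t1 <- nrow(counts[[1L]])
  lam1 <- discount * t1 / tot
  p1 <- pmax(counts[[1L]]$count - discount, 0) / tot + lam1 / nv
  for (i in seq_len(t1))
    assign(counts[[1L]]$gram[i], log10(p1[i]), envir = model$prob[[1L]])
  model$unk_log10 <- if (lam1 > 0) log10(lam1 / nv) else -Inf

  ## higher levels: split grams into (context, word), aggregate context mass
  for (k in seq(2L, length.out = max(order - 1L, 0L))) {
    ck <- counts[[k]]
    if (nrow(ck) == 0L) next
    sp <- split_gram(ck$gram)
    ctx_tot <- rowsum(ck$count, sp$context)
    ctx_n1 <- rowsum(rep(1L, nrow(ck)), sp$context)
    ctot <- stats::setNames(ctx_tot[, 1L], rownames(ctx_tot))
    cn1 <- stats::setNames(ctx_n1[, 1L], rownames(ctx_n1))
    lam <- discount * cn1 / ctot
    for (ctx in names(lam))
      assign(ctx, if (lam[[ctx]] > 0) log10(lam[[ctx]]) else -Inf,
             envir = model$bow[[k - 1L]])
    for (i in seq_len(nrow(ck))) {
      ctx <- sp$context[i]
      w <- sp$word[i]
      p <- pmax(ck$count[i] - discount, 0) / ctot[[ctx]] +
        lam[[ctx]] * ngram_prob(model, w,
                                tail(strsplit(ctx, " ", fixed = TRUE)[[1L]], -1L))
      assign(ck$gram[i], log10(p), envir = model$prob[[k]])
    }
  }
  model
}

table_counts <- function(grams) {
  if (length(grams) == 0L)
    return(data.frame(gram = character(0), count = numeric(0)))
  tb <- table(grams)
  data.frame(gram = names(tb), count = as.numeric(tb),
             stringsAsFactors = FALSE)
}

split_gram <- function(grams) {
  pos <- regexpr(" [^ ]+$", grams)
  list(context = substr(grams, 1L, pos - 1L),
       word = substr(grams, pos + 1L, nchar(grams)))
}

#' Conditional probability and next-token distribution from an n-gram model
#'
#' `ngram_prob()` evaluates \eqn{p(\mathrm{token} \mid \mathrm{context})}
#' by the standard backoff walk: use the longest matching stored n-gram,
#' multiplying in the backoff weights of the contexts that were shortened
#' away. `ngram_dist()` evaluates it for every vocabulary token, yielding
#' the full next-token distribution (which sums to one).
#'
#' @param model an `ngram_model`.
#' @param token a single token.
#' @param context character vector of preceding tokens; only the last
#'   `order - 1` are used, and shorter contexts are allowed.
#' @return `ngram_prob()`: a probability. `ngram_dist()`: a named numeric
#'   vector over the vocabulary.
#' @export
ngram_prob <- function(model, token, context = character(0)) {
  stopifnot(inherits(model, "ngram_model"))
  context <- as.character(context)
  if (length(context) > model$order - 1L)
    context <- tail(context, model$order - 1L)
  acc <- 0  # accumulated log10 backoff
  repeat {
    k <- length(context) + 1L
    lp <- get0(paste(c(context, token), collapse = " "),
               envir = model$prob[[k]], inherits = FALSE)
    if (!is.null(lp) && lp > -Inf) return(10^(acc + lp))
    if (k == 1L) return(if (model$unk_log10 > -Inf) 10^(acc + model$unk_log10) else 0)
    b <- get0(paste(context, collapse = " "), envir = model$bow[[k - 1L]],
              inherits = FALSE)
    if (!is.null(b)) {
      if (b == -Inf) return(0)
      acc <- acc + b
    }
    context <- context[-1L]
  }
}

#' @rdname ngram_prob
#' @export
ngram_dist <- function(model, context = character(0)) {
  v <- model$vocabulary
  p <- vapply(v, function(w) ngram_prob(model, w, context), 0)
  names(p) <- v
  p
}

#' @export
print.ngram_model <- function(x, ...) {
  cat("Backoff n-gram model (interpolated absolute discounting)\n")
  cat("  order:", x$order, " vocabulary:", length(x$vocabulary),
      " discount:", x$discount, "\n")
  for (k in seq_len(x$order))
    cat("  ", k, "-grams stored: ", length(ls(x$prob[[k]])), "\n", sep = "")
  invisible(x)
}
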