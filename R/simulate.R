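## ARPAbet-like phoneme symbol pool for synthetic lexicons
PHONEME_POOL <- c("AA", "AE", "AH", "AO", "EH", "ER", "IH", "IY", "UH",
                  "UW", "B", "D", "G", "K", "P", "T", "CH", "JH", "F",
                  "V", "S", "Z", "SH", "TH", "M", "N", "NG", "L", "R",
                  "W", "Y", "HH")

#' Generate a synthetic Zipf-frequency lexicon
#'
#' Builds a toy pronunciation lexicon with random transcriptions of 2-6
#' phonemes, Zipf-distributed frequency counts
#' (\eqn{f_r \propto r^{-s}}), and — by construction — at least one pair
#' of words sharing their first phoneme, so that incremental cohorts are
#' nontrivial. Deterministic given `seed`.
#'
#' @param n_words number of words (>= 2).
#' @param inventory_size number of phoneme symbols to use (>= 2; drawn
#'   from a fixed ARPAbet-like pool).
#' @param zipf_exponent Zipf exponent `s` (0 = near-uniform frequencies).
#' @param seed RNG seed.
#' @return A [lexicon()].
#' @export
make_lexicon <- function(n_words = 30, inventory_size = 12,
                         zipf_exponent = 1, seed = 1) {
  if (inventory_size < 2) stop("inventory must have at least 2 phonemes")
  if (n_words < 2) stop("lexicon must have at least 2 words")
  if (inventory_size > length(PHONEME_POOL))
    stop("at most ", length(PHONEME_POOL), " phoneme symbols available")
  inv <- PHONEME_POOL[seq_len(inventory_size)]
  ## a generous bound on distinct transcriptions of length 2..6
  if (sum(inventory_size^(2:6)) < n_words)
    stop("inventory too small to make ", n_words, " unique words")
  set.seed(seed)
  seen <- character(0)
  phonemes <- vector("list", n_words)
  for (i in seq_len(n_words)) {
    for (attempt in 1:1000) {
      len <- sample(2:6, 1L)
      tr <- sample(inv, len, replace = TRUE)
      ## force a shared first phoneme between the first two words
      if (i == 2L) tr[1L] <- phonemes[[1L]][1L]
      key <- paste(tr, collapse = " ")
      if (!key %in% seen) break
      if (attempt == 1000)
        stop("inventory too small to make unique words")
    }
    seen <- c(seen, key)
    phonemes[[i]] <- tr
  }
  freq <- pmax(round(1000 / seq_len(n_words)^zipf_exponent), 1)
  words <- sprintf("w%02d", seq_len(n_words))
  lexicon(words, phonemes, freq, inventory = inv)
}

#' Sample a word corpus and aligned event table
#'
#' Draws a word sequence from a first-order Markov chain over the lexicon
#' (rows of `transition` give p(next word | current word); the default is
#' frequency-weighted i.i.d. sampling) and lays the words' phonemes out
#' in time with gamma-distributed phoneme durations, yielding the token
#' sequence (for language-model training) and the time-aligned
#' [event_table()] that predictor construction consumes.
#'
#' @param lex a [lexicon()].
#' @param transition optional row-stochastic matrix over lexicon words.
#' @param n_words number of word tokens to sample.
#' @param timing list with `mean` (mean phoneme duration, seconds) and
#'   `shape` (gamma shape; larger = more regular).
#' @param seed RNG seed.
#' @return A list with `tokens` (character word sequence) and `events`
#'   (an `event_table`).
#' @export
make_corpus_and_events <- function(lex, transition = NULL, n_words = 500,
                                   timing = list(mean = 0.08, shape = 8),
                                   seed = 1) {
  stopifnot(inherits(lex, "lexicon"))
  nw <- nrow(lex)
  prior <- lex$frequency / sum(lex$frequency)
  if (is.null(transition))
    transition <- matrix(prior, nw, nw, byrow = TRUE)
  transition <- as.matrix(transition)
  if (nrow(transition) != nw || ncol(transition) != nw)
    stop("`transition` must be a square matrix over lexicon words")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("`transition` is not row-stochastic")
  set.seed(seed)
  idx <- integer(n_words)
  idx[1L] <- sample.int(nw, 1L, prob = prior)
  for (t in seq_len(n_words - 1L))
    idx[t + 1L] <- sample.int(nw, 1L, prob = transition[idx[t], ])
  tokens <- lex$word[idx]
  phon <- lex$phonemes[idx]
  n_ph <- sum(lengths(phon))
  durations <- stats::rgamma(n_ph, shape = timing$shape,
                             rate = timing$shape / timing$mean)
  onsets <- cumsum(c(0, durations[-n_ph]))
  total <- sum(durations)
  word_initial <- unlist(lapply(lengths(phon), function(L)
    c(TRUE, rep(FALSE, L - 1L))))
  events <- event_table(onsets, rep(tokens, lengths(phon)), unlist(phon),
                        word_initial, duration = total)
  list(tokens = tokens, events = events)
}

#' Ground-truth TRF kernels in the span of a basis
#'
#' Builds true kernels as sums of basis Hamming bumps at stated peak
#' latencies and amplitudes (so that recovery tests compare like with
#' like), with multiplicative log-normal per-source amplitude jitter.
#'
#' @param basis a [make_basis()] object.
#' @param kernel_spec a named list, one entry per predictor, each a data
#'   frame with columns `latency_ms` and `amplitude`.
#' @param n_sources number of response channels.
#' @param jitter standard deviation of the log-normal per-source,
#'   per-predictor amplitude jitter (0 = identical kernels everywhere).
#' @param seed RNG seed.
#' @return An object of class `"ground_truth"`: `coef` (predictor x
#'   basis x source array), `basis`, `kernel_spec`, `seed`.
#' @export
make_ground_truth <- function(basis, kernel_spec, n_sources = 4,
                              jitter = 0.2, seed = 1) {
  stopifnot(inherits(basis, "trf_basis"), is.list(kernel_spec))
  p <- length(kernel_spec)
  nb <- length(basis$centers_ms)
  set.seed(seed)
  coef <- array(0, c(p, nb, n_sources),
                dimnames = list(names(kernel_spec), NULL, NULL))
  for (i in seq_len(p)) {
    ks <- kernel_spec[[i]]
    if (nrow(ks) == 0L) next
    if (any(ks$latency_ms < basis$tmin_ms | ks$latency_ms >= basis$tmax_ms))
      stop("peak latency outside the basis window [", basis$tmin_ms, ", ",
           basis$tmax_ms, ") ms in predictor ", names(kernel_spec)[i])
    g <- if (jitter > 0) exp(stats::rnorm(n_sources, 0, jitter)) else
      rep(1, n_sources)
    for (r in seq_len(nrow(ks))) {
      j <- which.min(abs(basis$centers_ms - ks$latency_ms[r]))
      coef[i, j, ] <- coef[i, j, ] + ks$amplitude[r] * g
    }
  }
  structure(list(coef = coef, basis = basis, kernel_spec = kernel_spec,
                 n_sources = n_sources, jitter = jitter, seed = seed),
            class = "ground_truth")
}

#' Lag-domain kernels of a ground truth
#' @param truth a `ground_truth`.
#' @return Array `predictor x lag x source`.
#' @export
true_kernels <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  B <- basis_matrix(truth$basis)
  p <- dim(truth$coef)[1L]
  ker <- array(0, c(p, nrow(B), truth$n_sources),
               dimnames = list(dimnames(truth$coef)[[1L]], NULL, NULL))
  for (s in seq_len(truth$n_sources))
    ker[, , s] <- truth$coef[, , s] %*% t(B)
  ker
}

#' Band-limited 1/f^a colored noise
#'
#' Gaussian noise whose amplitude spectrum follows \eqn{f^{-a/2}} (power
#' \eqn{\propto f^{-a}}) inside `band` and is zero outside, emulating the
#' spectral shape of band-passed neural recordings. Scaled to unit
#' variance.
#'
#' @param n length in samples.
#' @param fs sampling rate (Hz).
#' @param exponent spectral exponent `a` (1 = pink).
#' @param band frequency band in Hz.
#' @export
colored_noise <- function(n, fs, exponent = 1, band = c(1, 10)) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  gain <- ifelse(f >= band[1L] & f <= band[2L], f^(-exponent / 2), 0)
  gain[1L] <- 0  # no DC
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate source responses from ground-truth kernels
#'
#' Runs the generative model of mTRF analysis forward: each source's
#' response is the sum over predictors of the true kernel convolved with
#' the predictor track, plus band-limited colored noise scaled to a
#' target signal-to-noise ratio, `SNR = var(signal) / var(noise)`.
#'
#' @param x predictors: a named list of [predictor_track()]s or a matrix.
#' @param truth a [make_ground_truth()] object (sharing the sampling
#'   rate of `x`).
#' @param fs sampling rate (required for a bare matrix).
#' @param snr target variance ratio (> 0); `Inf` for noiseless.
#' @param noise_exponent spectral exponent of the noise.
#' @param noise_band noise band in Hz.
#' @param seed RNG seed.
#' @return Matrix `time x source` of responses, with the noiseless
#'   signal in `attr(, "signal")`.
#' @export
simulate_responses <- function(x, truth, fs = NULL, snr = 1,
                               noise_exponent = 1, noise_band = c(1, 10),
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.infinite(snr) && snr <= 0) stop("`snr` must be > 0")
  px <- as_predictor_matrix(x, fs)
  if (!is.null(px$fs) && !isTRUE(all.equal(px$fs, truth$basis$fs)))
    stop("predictor and kernel sampling rates differ")
  X <- px$x
  n <- nrow(X)
  if (ncol(X) != dim(truth$coef)[1L])
    stop("predictor count does not match the ground truth")
  b <- truth$basis
  set.seed(seed)
  y <- matrix(0, n, truth$n_sources)
  for (s in seq_len(truth$n_sources))
    y[, s] <- predict_mtrf_cpp(X, coef_slice(truth$coef, s),
                               b$centers, b$window, b$win_offset,
                               0L, as.integer(n))
  signal <- y
  if (!is.infinite(snr)) {
    for (s in seq_len(truth$n_sources)) {
      nz <- colored_noise(n, b$fs, noise_exponent, noise_band)
      vs <- stats::var(signal[, s])
      scale <- if (vs > 0) sqrt(vs / snr) else 1
      y[, s] <- signal[, s] + scale * nz
    }
  }
  attr(y, "signal") <- signal
  y
}

#' Synthetic source-space geometry
#'
#' Two mirror-symmetric chains of sources, one per hemisphere, with unit
#' spacing, chain adjacency, and the natural left-right pairing — the
#' reduced stand-in for a cortical source grid used in simulations.
#'
#' @param n_per_hemisphere sources per hemisphere.
#' @param gap distance between the innermost sources of the hemispheres.
#' @return A [source_space()] with `2 * n_per_hemisphere` sources
#'   (left first).
#' @export
grid_space <- function(n_per_hemisphere = 10, gap = 6) {
  n <- n_per_hemisphere
  coords <- cbind(c(-(gap / 2 + seq_len(n)), gap / 2 + seq_len(n)),
                  rep(0, 2 * n))
  chain <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
           else matrix(integer(0), 0L, 2L)
  edges <- rbind(chain, chain + n)
  source_space(coords, edges, rep(c("L", "R"), each = n),
               pairing = c(n + seq_len(n), seq_len(n)))
}

#' Simulate per-subject source maps with an injected effect
#'
#' Draws per-subject scalar maps `effect + noise` (i.i.d. Gaussian per
#' source and subject) — the lightweight generator for calibrating and
#' power-testing the group-statistics layer directly at the map level.
#'
#' @param space a [source_space()].
#' @param n_subjects number of subjects.
#' @param effect scalar or per-source vector of true means.
#' @param sd noise standard deviation.
#' @param labels optional per-subject group labels.
#' @param seed RNG seed.
#' @return A [group_dataset()].
#' @export
simulate_source_maps <- function(space, n_subjects, effect = 0, sd = 1,
                                 labels = NULL, seed = 1) {
  stopifnot(inherits(space, "source_space"))
  set.seed(seed)
  effect <- rep_len(effect, space$n)
  maps <- matrix(stats::rnorm(n_subjects * space$n, sd = sd),
                 n_subjects, space$n)
  maps <- sweep(maps, 2L, effect, "+")
  if (is.null(labels)) labels <- rep("all", n_subjects)
  group_dataset(maps, labels, space)
}
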