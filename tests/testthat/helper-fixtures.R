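## shared fixtures, all built in code

## the cat/cap/dog toy lexicon used for hand-enumerated cohort values
toy_lexicon <- function() {
  lexicon(c("cat", "cap", "dog"),
          list(c("K", "AE", "T"), c("K", "AE", "P"), c("D", "AO", "G")),
          c(2, 1, 1))
}

## small event table: "cat dog cap" at fixed onsets
toy_events <- function() {
  event_table(onset = c(0.00, 0.10, 0.20, 0.35, 0.45, 0.55, 0.70, 0.80, 0.90),
              word = rep(c("cat", "dog", "cap"), each = 3),
              phoneme = c("K", "AE", "T", "D", "AO", "G", "K", "AE", "P"),
              word_initial = rep(c(TRUE, FALSE, FALSE), 3),
              duration = 1.0)
}

## compact basis + quick fixture for boosting tests (fast to fit)
small_basis <- function(fs = 50) make_basis(0, 300, 60, 20, fs)

## impulse predictors + response from known kernels on the small basis
small_boost_fixture <- function(n = 1500, p = 2, snr = Inf, seed = 1,
                                fs = 50) {
  set.seed(seed)
  b <- small_basis(fs)
  x <- matrix(0, n, p)
  for (i in seq_len(p))
    x[sample.int(n - 20, round(n / 12)), i] <- 1
  colnames(x) <- paste0("x", seq_len(p))
  ks <- lapply(seq_len(p), function(i)
    data.frame(latency_ms = c(60, 200) + 20 * (i - 1),
               amplitude = c(1, -0.6)))
  names(ks) <- colnames(x)
  truth <- make_ground_truth(b, ks, n_sources = 1, jitter = 0,
                             seed = seed + 1)
  y <- simulate_responses(x, truth, snr = snr, seed = seed + 2)
  list(x = x, y = y[, 1], basis = b, truth = truth, fs = fs)
}

## brute-force n-gram count oracle: MLE conditionals from raw counts
count_oracle_prob <- function(seqs, token, context) {
  if (is.character(seqs)) seqs <- list(seqs)
  k <- length(context)
  num <- 0L
  den <- 0L
  for (s in seqs) {
    n <- length(s)
    if (n < k + 1L) next
    for (t in seq_len(n - k)) {
      if (k == 0L || all(s[t:(t + k - 1L)] == context)) {
        den <- den + 1L
        if (s[t + k] == token) num <- num + 1L
      }
    }
  }
  if (den == 0L) return(NA_real_)
  num / den
}

## independent TFCE oracle: direct summation over thresholds with
## breadth-first component labeling (midpoint grid matching tfce())
tfce_oracle <- function(stat, edges, E, H, dh) {
  n <- length(stat)
  adj <- lapply(seq_len(n), function(i)
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  enh <- numeric(n)
  one_side <- function(v, sgn) {
    hmax <- max(v)
    if (hmax <= 0) return()
    thresholds <- c()
    h <- dh / 2
    while (h <= hmax) { thresholds <- c(thresholds, h); h <- h + dh }
    for (h in thresholds) {
      member <- v >= h
      seen <- rep(FALSE, n)
      for (s in which(member)) {
        if (seen[s]) next
        comp <- s
        queue <- s
        seen[s] <- TRUE
        while (length(queue)) {
          cur <- queue[1]; queue <- queue[-1]
          for (nb in adj[[cur]]) {
            if (member[nb] && !seen[nb]) {
              seen[nb] <- TRUE
              comp <- c(comp, nb)
              queue <- c(queue, nb)
            }
          }
        }
        enh[comp] <<- enh[comp] + sgn * length(comp)^E * h^H * dh
      }
    }
  }
  one_side(pmax(stat, 0), 1)
  one_side(pmax(-stat, 0), -1)
  enh
}

expect_near <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) < tol),
              label = paste0(deparse(substitute(object)), " near ",
                             deparse(substitute(expected))))
}
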