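test_that("synthetic lexicons are reproducible, Zipf-weighted, prefix-sharing", {
  l1 <- make_lexicon(n_words = 10, inventory_size = 6, seed = 4)
  l2 <- make_lexicon(n_words = 10, inventory_size = 6, seed = 4)
  expect_identical(l1, l2)
  expect_equal(l1$frequency[1] / l1$frequency[10], 10, tolerance = 0.05)
  # zero exponent: near-uniform
  l0 <- make_lexicon(n_words = 10, zipf_exponent = 0, seed = 4)
  expect_true(all(l0$frequency == l0$frequency[1]))
  # guaranteed shared first phoneme
  firsts <- vapply(l1$phonemes, `[[`, "", 1)
  expect_true(any(duplicated(firsts)))
  expect_error(make_lexicon(n_words = 2, inventory_size = 1), "at least 2")
})

test_that("sampled corpora respect timing and event-table invariants", {
  lex <- make_lexicon(n_words = 8, seed = 2)
  corp <- make_corpus_and_events(lex, n_words = 100,
                                 timing = list(mean = 0.08, shape = 8),
                                 seed = 3)
  ev <- corp$events
  expect_s3_class(ev, "event_table")
  expect_equal(length(corp$tokens), 100)
  expect_equal(sum(ev$word_initial), 100)
  expect_true(all(diff(ev$onset) > 0))
  # duration is the sum of the sampled phoneme durations
  expect_equal(attr(ev, "duration") / (nrow(ev) * 0.08), 1,
               tolerance = 0.15)
})

test_that("a deterministic cycle grammar yields a periodic word sequence", {
  lex <- make_lexicon(n_words = 3, seed = 5)
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  corp <- make_corpus_and_events(lex, transition = P, n_words = 12,
                                 seed = 1)
  ids <- match(corp$tokens, lex$word)
  expect_true(all(ids[4:12] == ids[1:9]))
  expect_error(make_corpus_and_events(lex, transition = P * 2,
                                      n_words = 5), "stochastic")
})

test_that("empirical transitions match the generating matrix (chi-square)", {
  lex <- make_lexicon(n_words = 4, seed = 6)
  P <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25,
                0.1, 0.2, 0.3, 0.4,
                0.4, 0.3, 0.2, 0.1), 4, 4, byrow = TRUE)
  corp <- make_corpus_and_events(lex, transition = P, n_words = 5000,
                                 seed = 7)
  ids <- match(corp$tokens, lex$word)
  for (from in 1:4) {
    nxt <- ids[which(ids[-length(ids)] == from) + 1L]
    tab <- tabulate(nxt, 4)
    expect_gt(stats::chisq.test(tab, p = P[from, ])$p.value, 0.01)
  }
})

test_that("ground-truth kernels live in the basis span with stated peaks", {
  b <- small_basis()
  ks <- list(a = data.frame(latency_ms = 100, amplitude = 2),
             z = data.frame(latency_ms = numeric(0),
                            amplitude = numeric(0)))
  tr <- make_ground_truth(b, ks, n_sources = 3, jitter = 0, seed = 1)
  k <- true_kernels(tr)
  lags <- (b$lag_min:b$lag_max) / b$fs * 1000
  expect_lte(abs(lags[which.max(k[1, , 1])] - 100), b$width_ms / 2)
  expect_true(all(k[2, , ] == 0))
  tr2 <- make_ground_truth(b, ks, n_sources = 3, jitter = 0, seed = 1)
  expect_identical(tr$coef, tr2$coef)
  ks_bad <- list(a = data.frame(latency_ms = 900, amplitude = 1))
  expect_error(make_ground_truth(b, ks_bad), "outside")
})

test_that("noiseless responses equal the convolution sum exactly", {
  fx <- small_boost_fixture(n = 900, p = 2, snr = Inf, seed = 12)
  y2 <- simulate_responses(fx$x, fx$truth, snr = Inf, seed = 99)
  expect_identical(attr(y2, "signal")[, 1], y2[, 1])
  # hand convolution oracle for one predictor/kernel
  k <- true_kernels(fx$truth)
  lagv <- fx$basis$lag_min:fx$basis$lag_max
  n <- nrow(fx$x)
  oracle <- numeric(n)
  for (t in which(fx$x[, 1] != 0))
    for (li in seq_along(lagv)) {
      tt <- t + lagv[li]
      if (tt >= 1 && tt <= n)
        oracle[tt] <- oracle[tt] + k[1, li, 1] * fx$x[t, 1]
    }
  x1only <- cbind(fx$x[, 1], 0 * fx$x[, 2])
  y1 <- simulate_responses(x1only, fx$truth, snr = Inf, seed = 1)
  expect_near(y1[, 1], oracle, tol = 1e-9)
})

test_that("colored noise has the stated band-limited 1/f spectrum", {
  set.seed(30)
  n <- 20000
  fs <- 100
  z <- colored_noise(n, fs, exponent = 1, band = c(1, 10))
  expect_equal(stats::sd(z), 1, tolerance = 1e-6)
  spec <- Mod(stats::fft(z))^2 / n
  f <- seq(0, fs, length.out = n + 1)[1:n]
  sel <- f >= 1.5 & f <= 9    # interior of the band
  fit <- stats::lm(log(spec[sel]) ~ log(f[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.15)
  expect_lt(max(spec[f > 10.5 & f < 50]), 1e-20)
})

test_that("realized SNR tracks the target across seeds", {
  fx <- small_boost_fixture(n = 2000, p = 2, snr = Inf, seed = 40)
  ratios <- sapply(1:20, function(s) {
    y <- simulate_responses(fx$x, fx$truth, snr = 2, seed = 500 + s)
    sig <- attr(y, "signal")[, 1]
    stats::var(sig) / stats::var(y[, 1] - sig)
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("group studies are pure functions of the spec and detect multipliers", {
  spec <- study_spec(n_per_group = 2, n_sources_per_hemisphere = 2,
                     n_words = 60, seed = 77)
  s1 <- simulate_group_study(spec)
  s2 <- simulate_group_study(spec)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$events, s2$events)
  expect_equal(length(s1$responses), 6)
  expect_equal(s1$space$n, 4)
  # hemisphere-specific multiplier doubles the right-hemisphere signal
  spec2 <- study_spec(n_per_group = 2, n_sources_per_hemisphere = 2,
                      n_words = 60, seed = 77,
                      groups = c("English", "Mandarin", "Sinhala"),
                      effect_multipliers = list(
                        English = c(L = 1, R = 2),
                        Mandarin = c(L = 1, R = 1),
                        Sinhala = c(L = 1, R = 1)))
  s3 <- simulate_group_study(spec2)
  expect_error(study_spec(effect_multipliers = list(English = c(L = -1, R = 1),
                                                    Mandarin = c(L = 1, R = 1),
                                                    Sinhala = c(L = 1, R = 1))),
               "nonnegative")
  expect_s3_class(s3, "group_study")
})
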