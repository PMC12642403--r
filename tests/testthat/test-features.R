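test_that("sublexical features match a brute-force count oracle", {
  set.seed(31)
  inv <- c("P", "T", "K", "A", "I")
  n <- 200
  phon <- sample(inv, n, replace = TRUE)
  onsets <- cumsum(runif(n, 0.05, 0.12))
  ev <- event_table(onsets, word = rep("w", n), phoneme = phon,
                    word_initial = c(TRUE, rep(FALSE, n - 1)),
                    duration = max(onsets) + 0.2)
  ord <- 3
  m <- train_ngram(phon, ord, discount = 0, pad = FALSE)
  fs <- sublexical_features(ev, m, base = 2)
  # brute-force oracle: count ratios with truncated context at the start
  for (k in sample(seq(ord, n), 25)) {
    ctx <- phon[(k - ord + 1):(k - 1)]
    p <- count_oracle_prob(phon, phon[k], ctx)
    expect_near(fs$surprisal[k], -log2(p))
    # entropy over the next-phoneme distribution after phoneme k
    ctx2 <- phon[(k - ord + 2):k]
    q <- vapply(m$vocabulary, function(w) ngram_prob(m, w, ctx2), 0)
    q <- q[q > 0]
    expect_near(fs$phoneme_entropy[k], -sum(q * log2(q)))
  }
  expect_true(all(fs$surprisal >= 0))
  expect_true(all(fs$phoneme_entropy >= 0))
  expect_true(all(is.na(fs$cohort_entropy)))
})

test_that("deterministic phonotactics yield zero surprisal", {
  phon <- rep(c("A", "B"), 30)  # A always followed by B and vice versa
  onsets <- seq(0, by = 0.08, length.out = 60)
  ev <- event_table(onsets, rep("w", 60), phon,
                    c(TRUE, rep(FALSE, 59)), duration = 5)
  m <- train_ngram(phon, 2, discount = 0)
  fs <- sublexical_features(ev, m, base = 2)
  expect_near(fs$surprisal[-1], 0)   # first event has no context
  expect_near(fs$phoneme_entropy, 0)
})

test_that("uniform two-phoneme model gives one bit everywhere", {
  phon <- c("A", "A", "B", "B")  # p(A|.) = p(B|.) = 1/2 for unigram
  m <- train_ngram(phon, 1, discount = 0)
  ev2 <- event_table(c(0, 0.1, 0.2, 0.3), rep("w", 4), c("A", "B", "A", "B"),
                     c(TRUE, FALSE, FALSE, FALSE), duration = 0.5)
  fs <- sublexical_features(ev2, m, base = 2)
  expect_near(fs$surprisal, 1)
  expect_near(fs$phoneme_entropy, 1)
})

test_that("unseen phonemes raise a vocabulary error", {
  m <- train_ngram(c("A", "B", "A"), 2)
  ev <- event_table(0, "w", "Z", TRUE, duration = 1)
  expect_error(sublexical_features(ev, m), "vocabulary")
})

test_that("single-word lexicon gives zero surprisal and entropies", {
  lex <- lexicon("cat", list(c("K", "AE", "T")), 5)
  ev <- event_table(c(0, 0.1, 0.2), rep("cat", 3), c("K", "AE", "T"),
                    c(TRUE, FALSE, FALSE), duration = 0.4)
  fs <- cohort_features(ev, lex)
  expect_near(fs$surprisal, 0)
  expect_near(fs$phoneme_entropy, 0)
  expect_near(fs$cohort_entropy, 0)
})

test_that("cohort features on cat/cap/dog match hand enumeration", {
  fs <- cohort_features(toy_events(), toy_lexicon(), base = 2)
  # word 1 = cat: K (p=.75), AE (p=1), T (p=2/3)
  expect_near(fs$surprisal[1:3], -log2(c(0.75, 1, 2 / 3)))
  # cohort entropy after K in bits
  expect_near(fs$cohort_entropy[1],
              -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)))
  expect_near(fs$cohort_entropy[2],
              -(2 / 3 * log2(2 / 3) + 1 / 3 * log2(1 / 3)))
  expect_near(fs$cohort_entropy[3], 0)  # only cat remains
  # word 2 = dog: D resolves the cohort immediately
  expect_near(fs$surprisal[4], -log2(0.25))
  expect_near(fs$cohort_entropy[4:6], 0)
  expect_false(any(fs$oov))
})

test_that("sentence-LM priors change word-initial surprisal as enumerated", {
  lex <- toy_lexicon()
  # hand-crafted word LM: after context, cat/cap/dog get .9/.05/.05
  lm <- structure(
    list(order = 1L, vocabulary = c("cap", "cat", "dog"),
         discount = 0,
         prob = list(new.env()), bow = list(new.env()),
         unk_log10 = -Inf, pad_symbol = NULL),
    class = "ngram_model")
  assign("cat", log10(0.9), envir = lm$prob[[1]])
  assign("cap", log10(0.05), envir = lm$prob[[1]])
  assign("dog", log10(0.05), envir = lm$prob[[1]])
  ev <- event_table(c(0, 0.1, 0.2), rep("cat", 3), c("K", "AE", "T"),
                    c(TRUE, FALSE, FALSE), duration = 0.4)
  fs <- cohort_features(ev, lex, "sentence", word_lm = lm, base = 2)
  expect_near(fs$surprisal[1], -log2(0.95), tol = 1e-9)
  expect_near(fs$surprisal[1], 0.0740006, tol = 1e-6)
})

test_that("single-phoneme words reduce cohort surprisal to unigram surprisal", {
  lex <- lexicon(c("a", "b", "c"), list("A", "B", "C"), c(5, 3, 2))
  n <- 60
  set.seed(8)
  ids <- sample(3, n, replace = TRUE, prob = c(5, 3, 2) / 10)
  ev <- event_table(seq(0, by = 0.1, length.out = n), lex$word[ids],
                    c("A", "B", "C")[ids], rep(TRUE, n), duration = n * 0.1)
  fs <- cohort_features(ev, lex)
  # unigram model with the lexicon frequencies as corpus is equivalent
  expected <- -log((c(5, 3, 2) / 10)[ids])
  expect_near(fs$surprisal, expected)
})

test_that("missing lexicon words are reported by name", {
  ev <- event_table(0, "zebra", "Z", TRUE, duration = 1)
  expect_error(cohort_features(ev, toy_lexicon()), "zebra")
})
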