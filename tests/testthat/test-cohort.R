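test_that("frequency prior normalizes over the lexicon", {
  st <- cohort_init(toy_lexicon())
  expect_near(st$probs, c(0.5, 0.25, 0.25))
  expect_setequal(st$words, c("cat", "cap", "dog"))
})

test_that("uniform and degenerate priors behave as stated", {
  lex <- toy_lexicon()
  st <- cohort_init(lex, prior = rep(1, 3))
  expect_near(st$probs, rep(1 / 3, 3))
  st1 <- cohort_init(lex, prior = c(1, 0, 0))
  expect_equal(st1$words, "cat")
  expect_near(st1$probs, 1)
  expect_error(cohort_init(lex, prior = c(0, 0, 0)), "all zero")
})

test_that("cohort updates match hand enumeration on cat/cap/dog", {
  st <- cohort_init(toy_lexicon())
  u1 <- cohort_update(st, "K")
  expect_near(u1$p_phoneme, 0.75)
  expect_near(u1$state$probs, c(2 / 3, 1 / 3))
  expect_setequal(u1$state$words, c("cat", "cap"))

  u2 <- cohort_update(u1$state, "AE")
  expect_near(u2$p_phoneme, 1)
  expect_near(u2$state$probs, c(2 / 3, 1 / 3))

  u3 <- cohort_update(u2$state, "T")
  expect_near(u3$p_phoneme, 2 / 3)
  expect_near(-log2(u3$p_phoneme), 0.5849625, tol = 1e-6)
  expect_equal(u3$state$words, "cat")
  expect_near(u3$state$probs, 1)
})

test_that("cohort word entropy after K matches the hand value in nats", {
  st <- cohort_init(toy_lexicon())
  u1 <- cohort_update(st, "K")
  expect_near(cohort_entropy(u1$state),
              -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)), tol = 1e-9)
  expect_near(cohort_entropy(u1$state), 0.6365142, tol = 1e-6)
})

test_that("update conserves probability: p(phoneme) = 1 - eliminated mass", {
  set.seed(21)
  for (rep in 1:20) {
    lex <- make_lexicon(n_words = 12, inventory_size = 6, seed = rep)
    st <- cohort_init(lex)
    w <- sample(lex$word, 1)
    tr <- lex$phonemes[[match(w, lex$word)]]
    for (ph in tr) {
      before <- sum(st$probs)
      expect_near(before, 1)
      up <- cohort_update(st, ph)
      if (!up$oov) {
        pos <- st$consumed + 1L
        nxt <- vapply(st$transcriptions, function(x)
          if (length(x) >= pos) x[pos] else NA_character_, "")
        eliminated <- sum(st$probs[is.na(nxt) | nxt != ph])
        expect_near(up$p_phoneme, 1 - eliminated)
        expect_near(sum(up$state$probs), 1)
      }
      st <- up$state
    }
  }
})

test_that("out-of-cohort phonemes trigger the flagged uniform fallback", {
  lex <- toy_lexicon()
  st <- cohort_init(lex)
  up <- cohort_update(st, "Z")  # no candidate starts with Z
  expect_true(up$oov)
  expect_near(up$p_phoneme, 1 / length(phoneme_inventory(lex)))
  expect_equal(cohort_entropy(up$state), 0)
  # subsequent phonemes stay in fallback
  up2 <- cohort_update(up$state, "AE")
  expect_true(up2$oov)
  q <- cohort_next_phoneme_dist(up2$state)
  expect_near(q, rep(1 / length(q), length(q)))
})

test_that("next-phoneme distribution aggregates candidate mass", {
  st <- cohort_init(toy_lexicon())
  q <- cohort_next_phoneme_dist(st)
  expect_near(q[["K"]], 0.75)
  expect_near(q[["D"]], 0.25)
  expect_near(sum(q), 1)
  # after cat completes, no continuation remains
  st3 <- cohort_update(cohort_update(cohort_update(st, "K")$state,
                                     "AE")$state, "T")$state
  expect_near(sum(cohort_next_phoneme_dist(st3)), 0)
})

test_that("removing a supporting word cannot decrease surprisal", {
  # prior fixed on remaining words; removing 'cap' makes K less probable
  lex3 <- toy_lexicon()
  lex2 <- lexicon(c("cat", "dog"),
                  list(c("K", "AE", "T"), c("D", "AO", "G")), c(2, 1),
                  inventory = phoneme_inventory(lex3))
  p3 <- cohort_update(cohort_init(lex3, c(2, 1, 1)), "K")$p_phoneme
  p2 <- cohort_update(cohort_init(lex2, c(2, 1)), "K")$p_phoneme
  expect_lte(-log(p3), -log(p2) + 1e-12)
})
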