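test_that("bigram conditionals on a printed string match hand counts", {
  m <- train_ngram(strsplit("A B A B A C", " ")[[1]], order = 2)
  expect_near(ngram_prob(m, "B", "A"), 2 / 3)
  expect_near(ngram_prob(m, "C", "A"), 1 / 3)
  expect_near(ngram_prob(m, "A", "B"), 1)
})

test_that("order-1 model reduces to relative frequency", {
  toks <- c("A", "A", "B", "C", "A")
  m <- train_ngram(toks, order = 1)
  expect_near(ngram_prob(m, "A"), 3 / 5)
  expect_near(ngram_prob(m, "B"), 1 / 5)
})

test_that("degenerate single-symbol corpus gives certainty", {
  m <- train_ngram(c("X", "X", "X"), order = 2)
  expect_near(ngram_prob(m, "X", "X"), 1)
})

test_that("input validation catches empty corpora and excessive order", {
  expect_error(train_ngram(list(), 2), "empty")
  expect_error(train_ngram(character(0), 1), "empty")
  expect_error(train_ngram(c("A", "B"), order = 4), "exceeds")
  expect_error(train_ngram(c("A", "B"), order = 2, discount = 1),
               "discount")
})

test_that("discount-0 models match the count-ratio oracle on random corpora", {
  set.seed(11)
  for (rep in 1:50) {
    nsym <- sample(2:8, 1)
    syms <- LETTERS[seq_len(nsym)]
    len <- sample(30:500, 1)
    toks <- sample(syms, len, replace = TRUE)
    ord <- sample(1:3, 1)
    m <- train_ngram(toks, ord, discount = 0)
    # probe several seen contexts
    for (probe in 1:5) {
      t0 <- sample(seq_len(len - ord), 1)
      ctx <- if (ord > 1) toks[t0:(t0 + ord - 2)] else character(0)
      tok <- toks[t0 + ord - 1]
      expect_near(ngram_prob(m, tok, ctx),
                  count_oracle_prob(toks, tok, ctx))
    }
  }
})

test_that("next-token distributions sum to one for seen and unseen contexts", {
  set.seed(5)
  toks <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  for (d in c(0, 0.3, 0.7)) {
    m <- train_ngram(toks, 3, discount = d)
    expect_near(sum(ngram_dist(m, c("a", "b"))), 1)
    expect_near(sum(ngram_dist(m, c("zz", "a"))), 1)  # backoff path
    expect_near(sum(ngram_dist(m, character(0))), 1)
  }
})

test_that("padding gives full-length contexts at sequence starts", {
  m <- train_ngram(list(c("A", "B"), c("A", "C")), order = 2,
                   discount = 0, pad = TRUE)
  # both sequences start with A after the pad context
  expect_near(ngram_prob(m, "A", "<s>"), 1)
  expect_near(ngram_prob(m, "B", "A"), 1 / 2)
})

test_that("ARPA serialization round-trips probabilities", {
  set.seed(9)
  toks <- sample(c("the", "cat", "sat", "mat"), 120, replace = TRUE)
  m <- train_ngram(toks, 3, discount = 0.4)
  path <- withr::local_tempfile(fileext = ".arpa")
  write_arpa(m, path)
  m2 <- read_arpa(path)
  expect_setequal(m2$vocabulary, m$vocabulary)
  for (ctx in list(character(0), "the", c("the", "cat"), c("cat", "zz"))) {
    p1 <- ngram_dist(m, ctx)
    p2 <- ngram_dist(m2, ctx)[names(p1)]
    expect_true(all(abs(log10(p1) - log10(p2)) < 1e-6))
  }
})

test_that("ARPA queries on unseen contexts follow the backoff path", {
  # hand-built bigram ARPA file: p(b|a) stored; p(c|a) backs off
  lines <- c("\\data\\", "ngram 1=3", "ngram 2=1", "",
             "\\1-grams:",
             "-0.3010300\ta\t-0.3979400",
             "-0.4771213\tb",
             "-0.4771213\tc", "",
             "\\2-grams:",
             "-0.0969100\ta b", "",
             "\\end\\")
  path <- withr::local_tempfile(fileext = ".arpa")
  writeLines(lines, path)
  m <- read_arpa(path)
  expect_near(ngram_prob(m, "b", "a"), 10^-0.09691, tol = 1e-7)
  # unseen bigram (a c): bow(a) * p(c) = 10^-0.39794 * 10^-0.4771213
  expect_near(ngram_prob(m, "c", "a"), 10^(-0.39794 - 0.4771213),
              tol = 1e-7)
})

test_that("malformed ARPA files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".arpa")
  writeLines(c("\\1-grams:", "-1 a"), path)
  expect_error(read_arpa(path), "data")
  writeLines(c("\\data\\", "ngram 1=xx", "", "\\1-grams:", "-1 a",
               "\\end\\"), path)
  expect_error(read_arpa(path), "count line")
})
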