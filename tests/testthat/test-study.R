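## one small simulated study shared by the pipeline-level tests
tiny_study <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- study_spec(n_per_group = 2, groups = c("English", "Mandarin"),
                         n_sources_per_hemisphere = 1, n_words = 220,
                         snr = 2, jitter = 0.1, seed = 5)
      memo <<- simulate_group_study(spec)
    }
    memo
  }
})

test_that("build_predictors returns aligned tracks for requested features", {
  lex <- make_lexicon(n_words = 12, seed = 9)
  corp <- make_corpus_and_events(lex, n_words = 80, seed = 10)
  feats <- c("word_onset", "phoneme_onset", "sublexical_surprisal",
             "lexical_surprisal", "lexical_cohort_entropy",
             "sentence_surprisal")
  x <- build_predictors(corp$events, lex, fs = 100, features = feats)
  expect_equal(names(x), feats)
  lens <- vapply(x, function(t) length(t$values), 0L)
  expect_equal(length(unique(lens)), 1L)
  expect_equal(sum(x$word_onset$values), 80)
  # surprisal impulses sit at phoneme onsets with nonnegative mass
  expect_true(all(x$sublexical_surprisal$values >= 0))
  expect_error(build_predictors(corp$events, NULL, features = feats),
               "lexicon")
})

test_that("the full improvement protocol recovers signal and group nulls", {
  study <- tiny_study()
  res <- run_improvement_study(study, omit = "sublexical_surprisal",
                               k = 4)
  # the omitted predictor truly drives the response everywhere
  expect_true(all(res$delta$maps > 0))
  expect_equal(dim(res$delta$maps), c(4L, 2L))
  expect_equal(nrow(res$roi_table), 4)  # 2 groups x 2 hemispheres
  expect_true(all(res$roi_table$mean > 0))
  expect_s3_class(res$regressions$L, "language_regression")
  expect_true(all(is.finite(res$li)))
})

test_that("mtrf objects expose the standard modelling interface", {
  study <- tiny_study()
  fit <- mtrf(study$predictors, study$responses[[1]], k = 4)
  expect_s3_class(fit, "mtrf")
  expect_output(print(fit), "quality index")
  s <- summary(fit)
  expect_output(print(s), "Per-source")
  k <- coef(fit)
  expect_equal(dim(k)[1], 3)
  expect_equal(dim(k)[3], 2)
  # predict on the training data matches the stored fitted values
  pr <- predict(fit, newdata = study$predictors)
  expect_equal(dim(pr), dim(study$responses[[1]]))
  res <- residuals(fit)
  expect_equal(study$responses[[1]] - predict(fit), res)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), dim(res))
})

test_that("predict matches a direct convolution with the averaged kernels", {
  study <- tiny_study()
  fit <- mtrf(study$predictors, study$responses[[1]][, 1], k = 4)
  x <- sapply(study$predictors, `[[`, "values")
  p1 <- predict(fit, newdata = x)[, 1]
  # oracle: standardize with the recorded parameters, convolve with the
  # lag-domain kernels, undo the response standardization
  Xs <- sweep(sweep(x, 2, fit$x_center), 2, fit$x_scale, "/")
  ker <- coef(fit)[, , 1]
  lags <- fit$basis$lag_min:fit$basis$lag_max
  n <- nrow(Xs)
  yh <- numeric(n)
  for (i in seq_len(ncol(Xs)))
    for (li in seq_along(lags)) {
      if (ker[i, li] == 0) next
      src <- seq_len(n) - lags[li]
      ok <- src >= 1 & src <= n
      yh[ok] <- yh[ok] + ker[i, li] * Xs[src[ok], i]
    }
  expect_near(p1, yh * fit$y_scale[1] + fit$y_center[1], tol = 1e-6)
})
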