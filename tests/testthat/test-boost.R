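## fast fit on the small fixture, shared across expectations
fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      fx <- small_boost_fixture(n = 1500, p = 2, snr = Inf, seed = 3)
      memo <<- list(fx = fx, fit = mtrf(fx$x, fx$y, fs = fx$fs,
                                        basis = fx$basis))
    }
    memo
  }
})

test_that("noiseless kernels are recovered with high fidelity", {
  m <- fit_small()
  ker <- coef(m$fit)
  tk <- true_kernels(m$fx$truth)
  for (i in 1:2)
    expect_gte(cor(ker[i, , 1], tk[i, , 1]), 0.95)
  expect_gte(m$fit$quality[1], 0.7)
})

test_that("the quality index is exact at its anchor points", {
  y <- rnorm(100)
  expect_equal(quality_index(y, y), 1)
  expect_equal(quality_index(y, rep(0, 100)), 0)
  expect_lt(quality_index(y, -y), 0)
})

test_that("prediction is linear and reproduces basis bumps from impulses", {
  b <- small_basis()
  n <- 800
  x1 <- matrix(0, n, 1)
  x1[100, 1] <- 1
  cf <- matrix(0, 1, length(b$centers))
  cf[1, 5] <- 1
  yh <- predict_mtrf_cpp(x1, cf, b$centers, b$window, b$win_offset,
                         0L, as.integer(n))
  c5 <- b$centers[5]
  lag0 <- 100 + c5 - b$win_offset
  L <- length(b$window)
  expect_near(yh[lag0 + seq_len(L) - 1], b$window)
  expect_near(sum(yh != 0), L)
  # linearity: predict(x1 + x2) = predict(x1) + predict(x2)
  x2 <- matrix(0, n, 1)
  x2[300, 1] <- 2
  yh12 <- predict_mtrf_cpp(x1 + x2, cf, b$centers, b$window, b$win_offset,
                           0L, as.integer(n))
  yh2 <- predict_mtrf_cpp(x2, cf, b$centers, b$window, b$win_offset,
                          0L, as.integer(n))
  expect_near(yh12, yh + yh2)
  # all-zero coefficients predict zero
  expect_true(all(predict_mtrf_cpp(x1, 0 * cf, b$centers, b$window,
                                   b$win_offset, 0L, as.integer(n)) == 0))
})

test_that("pure-noise responses yield near-null fits", {
  set.seed(17)
  fx <- small_boost_fixture(n = 1500, p = 2, snr = Inf, seed = 5)
  y_noise <- rnorm(length(fx$y))
  fit <- mtrf(fx$x, y_noise, fs = fx$fs, basis = fx$basis)
  expect_lte(fit$quality[1], 0.02)
  expect_lte(max(abs(coef(fit))), 0.2 * max(abs(true_kernels(fx$truth))))
})

test_that("fits are deterministic: identical inputs give identical coefficients", {
  fx <- small_boost_fixture(n = 1200, p = 2, snr = 3, seed = 9)
  f1 <- mtrf(fx$x, fx$y, fs = fx$fs, basis = fx$basis)
  f2 <- mtrf(fx$x, fx$y, fs = fx$fs, basis = fx$basis)
  expect_identical(f1$coef, f2$coef)
  expect_identical(f1$quality, f2$quality)
})

test_that("training error is non-increasing over accepted steps and the freeze log replays", {
  fx <- small_boost_fixture(n = 1200, p = 2, snr = 2, seed = 13)
  X <- sapply(seq_len(ncol(fx$x)), function(i) standardize(fx$x[, i])$values)
  ys <- standardize(fx$y)$values
  part <- speechtrf:::cv_partition(nrow(X), 4)
  bf <- boost_fit(X, ys, part, train = c(1, 2), validation = 3, fx$basis)
  log <- bf$log
  acc <- log[log$accepted == 1, ]
  expect_true(all(diff(acc$train_err) <= 1e-9))
  # replaying the accepted steps reproduces the final coefficients
  cf <- matrix(0, ncol(X), length(fx$basis$centers))
  for (r in seq_len(nrow(acc)))
    cf[acc$predictor[r], acc$basis[r]] <-
      cf[acc$predictor[r], acc$basis[r]] + acc$sign[r] * bf$step
  expect_near(cf, bf$coef, tol = 1e-12)
})

sham_run <- function(snr, s) {
  fx <- small_boost_fixture(n = 1200, p = 1, snr = snr, seed = 100 + s)
  set.seed(1000 + s)
  x2 <- cbind(fx$x, sham = 0)
  x2[sample.int(nrow(x2) - 20, round(nrow(x2) / 12)), 2] <- 1
  X <- sapply(1:2, function(i) standardize(x2[, i])$values)
  ys <- standardize(fx$y)$values
  part <- speechtrf:::cv_partition(nrow(X), 4)
  boost_fit(X, ys, part, train = c(1, 2), validation = 3, fx$basis)
}

test_that("sham predictors freeze no later than informative ones (noiseless)", {
  n_runs <- 20
  wins <- 0
  for (s in seq_len(n_runs)) {
    bf <- sham_run(Inf, s)
    log <- bf$log
    freeze_iter <- function(p) {
      i <- log$iter[log$accepted == 0 & log$predictor == p]
      if (length(i)) min(i) else max(log$iter) + 1L
    }
    if (freeze_iter(2) <= freeze_iter(1)) wins <- wins + 1
  }
  expect_gte(wins / n_runs, 0.9)
})

test_that("validation freezing keeps sham kernel mass near zero under noise", {
  ratios <- sapply(1:10, function(s) {
    bf <- sham_run(2, s)
    sum(abs(bf$coef[2, ])) / max(sum(abs(bf$coef[1, ])), 1e-12)
  })
  expect_lt(mean(ratios), 0.1)
})

test_that("validation freezing returns an all-zero fit when nothing helps at start", {
  # response orthogonal to a predictor that never fires
  b <- small_basis()
  n <- 800
  x <- matrix(0, n, 1)  # all-zero predictor: no step can reduce error
  y <- rnorm(n)
  part <- speechtrf:::cv_partition(n, 4)
  bf <- boost_fit(x, y, part, train = c(1, 2), validation = 3, b)
  expect_true(all(bf$coef == 0))
})

test_that("model improvement is zero when reduced equals full and errors on non-subsets", {
  fx <- small_boost_fixture(n = 1200, p = 2, snr = 5, seed = 23)
  imp <- mtrf_improvement(fx$x, fx$y, reduced = colnames(fx$x),
                          fs = fx$fs, basis = fx$basis)
  expect_equal(imp$delta, rep(0, length(imp$delta)))
  expect_error(mtrf_improvement(fx$x, fx$y, reduced = c("x1", "zz"),
                                fs = fx$fs, basis = fx$basis), "subset")
})

test_that("omitting an informative predictor costs predictive power", {
  fx <- small_boost_fixture(n = 1500, p = 2, snr = 5, seed = 29)
  imp <- mtrf_improvement(fx$x, fx$y, reduced = "x1", fs = fx$fs,
                          basis = fx$basis)
  expect_gt(imp$delta[1], 0.01)
})
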