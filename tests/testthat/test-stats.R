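test_that("one-sample TFCE test handles degenerate equal maps via the guard", {
  sp <- grid_space(4)
  maps <- matrix(0.5, nrow = 6, ncol = 8)  # identical positive maps
  r <- mass_univariate_onesample(maps, sp, sigma = 0, seed = 1)
  expect_true(all(is.finite(r$t)))
  # smallest attainable p under exhaustive flips (identity + full flip tie)
  expect_lte(r$p_cluster, 2 / 2^6 + 1e-12)
})

test_that("an injected localized effect is detected with high power", {
  sp <- grid_space(10)
  hits <- mean(sapply(1:25, function(s) {
    ds <- simulate_source_maps(sp, 12, effect = c(rep(1, 4), rep(0, 16)),
                               sd = 1, seed = 400 + s)
    r <- mass_univariate_onesample(ds, sigma = 1, seed = s)
    min(r$p) <= 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("exhaustive and random sign-flip enumerations agree on p", {
  sp <- grid_space(10)
  ds <- simulate_source_maps(sp, 11, effect = 0.45, sd = 1, seed = 5)
  r_ex <- mass_univariate_onesample(ds, sigma = 1, seed = 1)
  expect_true(r_ex$exhaustive)
  r_rand <- mass_univariate_onesample(ds, sigma = 1, seed = 2,
                                      n_perm = 10000L,
                                      exhaustive_limit = 2L)
  expect_false(r_rand$exhaustive)
  expect_lt(abs(min(r_rand$p) - min(r_ex$p)), 0.01)
  expect_lt(abs(r_rand$p_cluster - r_ex$p_cluster), 0.01)
})

test_that("hemispheric test is null for symmetric data and signed correctly", {
  sp <- grid_space(6)
  set.seed(9)
  half <- matrix(rnorm(10 * 6), 10, 6)
  maps <- cbind(half, half)  # right = left exactly
  h <- hemispheric_paired_test(group_dataset(maps, rep("g", 10), sp),
                               sigma = 0, seed = 1)
  expect_true(all(h$t == 0))
  expect_true(all(h$p >= 0.999))
  # right twice the left: differences negative -> tmax negative
  maps2 <- cbind(half, 2 * half)
  h2 <- hemispheric_paired_test(group_dataset(maps2, rep("g", 10), sp),
                                sigma = 0, seed = 1)
  maps3 <- cbind(2 * half, half)
  h3 <- hemispheric_paired_test(group_dataset(maps3, rep("g", 10), sp),
                                sigma = 0, seed = 1)
  expect_near(h2$t, -h3$t)
})

test_that("a simulated rightward doubling is detected in most runs", {
  sp <- grid_space(6)
  hits <- mean(sapply(1:20, function(s) {
    set.seed(700 + s)
    base <- matrix(rnorm(12 * 6, mean = 1, sd = 0.3), 12, 6)
    maps <- cbind(base, 2 * base) +
      matrix(rnorm(12 * 12, sd = 0.2), 12, 12)
    h <- hemispheric_paired_test(group_dataset(maps, rep("g", 12), sp),
                                 sigma = 0, seed = s)
    min(h$p) <= 0.05 && h$tmax < 0
  }))
  expect_gte(hits, 0.8)
})

test_that("ROI summaries average within the mask and flag degenerate cases", {
  maps <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(0, 1, 2, 3))
  rs <- roi_summary(maps, roi = c(TRUE, TRUE, FALSE, FALSE))
  expect_near(rs$subject_means, c(1.5, 2.5, 0.5))
  expect_equal(rs$test$df, 2)
  # antisymmetry
  rs_neg <- roi_summary(-maps, roi = c(TRUE, TRUE, FALSE, FALSE))
  expect_near(rs_neg$test$t, -rs$test$t)
  # degenerate: all subjects identical
  rs_deg <- roi_summary(matrix(2, 4, 3))
  expect_true(rs_deg$test$degenerate)
  expect_true(is.na(rs_deg$test$t))
  expect_error(roi_summary(maps, roi = c(FALSE, FALSE, FALSE, FALSE)),
               "empty")
})

test_that("ROI one-sample test rejects reliably under a true effect", {
  hits <- mean(sapply(1:60, function(s) {
    set.seed(s)
    maps <- matrix(rnorm(24 * 5, mean = 0.3, sd = 0.1), 24, 5)
    roi_summary(maps)$test$p < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("group regression uses the stated baseline and shifts only the intercept", {
  set.seed(3)
  v <- rnorm(36)
  l <- rep(c("English", "Mandarin", "Sinhala"), each = 12)
  r <- language_regression(v, l)
  expect_equal(r$baseline, "English")
  expect_setequal(r$coefficients$level, c("Mandarin", "Sinhala"))
  r_shift <- language_regression(v + 5, l)
  expect_near(r_shift$coefficients$estimate, r$coefficients$estimate)
  expect_near(r_shift$intercept, r$intercept + 5)
  expect_error(language_regression(v[1:12], l[1:12]), "2 groups")
})

test_that("regression coefficients recover an injected group offset", {
  cover <- mean(sapply(1:100, function(s) {
    set.seed(s)
    v <- rnorm(36, sd = 0.5)
    l <- rep(c("English", "Mandarin", "Sinhala"), each = 12)
    v[13:24] <- v[13:24] + 0.8
    r <- language_regression(v, l)
    est <- r$coefficients[r$coefficients$level == "Mandarin", ]
    se <- abs(est$estimate / est$t)
    abs(est$estimate - 0.8) <= 2 * se
  }))
  expect_gte(cover, 0.93)
})

test_that("two-group regression t equals the pooled pairwise t", {
  set.seed(4)
  v <- rnorm(24)
  l <- rep(c("English", "Mandarin"), each = 12)
  r <- language_regression(v, l)
  pt <- pairwise_language_ttests(v, l)
  expect_near(abs(r$coefficients$t), abs(pt$t), tol = 1e-10)
  # swapping group order negates the statistic
  pt_sw <- pairwise_language_ttests(v, factor(l, levels = c("Mandarin",
                                                            "English")))
  expect_near(pt_sw$t, -pt$t)
})

test_that("pairwise tests cover all pairs and skip tiny groups with a warning", {
  set.seed(6)
  v <- rnorm(25)
  l <- c(rep("A", 12), rep("B", 12), "C")
  warns <- capture_warnings(tab <- pairwise_language_ttests(v, l))
  expect_length(warns, 2)  # A-C and B-C both skipped
  expect_match(warns, "fewer than 2", all = TRUE)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$df, 22)
})

test_that("lateralization index hits its endpoints and is scale invariant", {
  expect_equal(lateralization_index(1, 1)[1], 0.5)
  expect_equal(lateralization_index(0, 2)[1], 1)
  expect_equal(lateralization_index(3, 0)[1], 0)
  set.seed(10)
  L <- runif(20); R <- runif(20)
  expect_near(lateralization_index(3.7 * L, 3.7 * R),
              lateralization_index(L, R))
  li <- lateralization_index(-0.2, 0.5)
  expect_equal(li[1], 1)
  expect_true(attr(li, "clipped")[1])
  expect_true(is.na(lateralization_index(0, 0)[1]))
})
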