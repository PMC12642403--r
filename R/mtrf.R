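## ---- internal plumbing -----------------------------------------------------

## predictor x basis matrix for one source from a 3-d coefficient array
coef_slice <- function(arr, s) {
  matrix(arr[, , s], dim(arr)[1L], dim(arr)[2L])
}

## Accept predictors as a named list of predictor_track objects or a
## numeric matrix; return list(x = matrix, names, fs)
as_predictor_matrix <- function(x, fs = NULL) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "predictor_track"))) {
    rates <- unique(vapply(x, `[[`, 0, "fs"))
    if (length(rates) != 1L)
      stop("predictor tracks have mismatched sampling rates")
    if (!is.null(fs) && !isTRUE(all.equal(fs, rates)))
      stop("predictor sampling rate (", rates,
           ") does not match `fs` (", fs, ")")
    lens <- unique(vapply(x, function(t) length(t$values), 0L))
    if (length(lens) != 1L)
      stop("predictor tracks have mismatched lengths")
    nm <- vapply(x, `[[`, "", "name")
    if (is.null(names(x)) || any(!nzchar(names(x)))) names(x) <- nm
    m <- vapply(x, `[[`, numeric(lens), "values")
    list(x = m, names = colnames(m), fs = rates)
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m)))
      colnames(m) <- paste0("x", seq_len(ncol(m)))
    list(x = m, names = colnames(m), fs = fs)
  }
}

## Fourfold (or k-fold) contiguous partition; 0-based [start, end) bounds.
## A remainder that k does not divide is assigned to the last segment.
cv_partition <- function(n, k = 4L) {
  if (n < k) stop("response too short for ", k, " segments")
  base <- n %/% k
  starts <- as.integer((seq_len(k) - 1L) * base)
  ends <- c(starts[-1L], as.integer(n))
  structure(list(k = as.integer(k), start = starts, end = ends,
                 remainder = as.integer(n - k * base)),
            class = "cv_partition")
}

## The three (train pair, validation) rotations for one test segment
cv_rotations <- function(k, test) {
  others <- setdiff(seq_len(k), test)
  lapply(others, function(v) list(train = setdiff(others, v), val = v))
}

## ---- exported operations ---------------------------------------------------

#' Model quality index
#'
#' \eqn{1 - \ell_1(\mathrm{residuals}) / \ell_1(y)}: 1 for a perfect
#' prediction, 0 for the null (all-zero) prediction, negative if the
#' prediction is worse than predicting zero. The improvement of a full
#' over a reduced model is the difference of their indices.
#'
#' @param y observed response vector.
#' @param yhat predicted response vector.
#' @export
quality_index <- function(y, yhat) {
  1 - sum(abs(y - yhat)) / sum(abs(y))
}

#' Single boosting run (steepest l1 coordinate descent with freezing)
#'
#' One training run of the boosting estimator on standardized inputs: at
#' each iteration every unfrozen (predictor, basis element) coordinate is
#' probed with `+step` and `-step`, the change with the maximum l1 error
#' reduction on the training segments is applied, and whenever a step
#' increases the l1 error on the validation segment it is reverted and the
#' responsible predictor's TRF is frozen. Training continues until the
#' whole mTRF is frozen. Ties in the steepest selection resolve to the
#' lowest predictor index, then the earliest lag, then the positive sign.
#'
#' This is the inner engine; [mtrf()] wraps it in standardization and
#' fourfold cross-validation.
#'
#' @param x numeric predictor matrix (time x predictor), standardized.
#' @param y numeric response vector, standardized.
#' @param partition a `cv_partition` (see [mtrf()] internals) or a list
#'   with 0-based `start`/`end` segment bounds.
#' @param train integer ids of the two training segments.
#' @param validation integer id of the validation segment.
#' @param basis a [make_basis()] object.
#' @param step coordinate step size (on the standardized scale).
#' @param max_iter safety cap on iterations.
#' @return A list of class `"boost_fit"`: `coef` (predictor x basis
#'   element), `log` (one row per iteration: coordinate probed, sign,
#'   accepted flag, training and validation l1 error), `n_iter`.
#' @export
boost_fit <- function(x, y, partition, train, validation, basis,
                      step = 0.005, max_iter = 100000L) {
  stopifnot(inherits(basis, "trf_basis"))
  x <- as.matrix(x)
  if (step <= 0) stop("`step` must be > 0")
  if (length(intersect(train, validation)))
    stop("validation segment must not be a training segment")
  res <- boost_run_cpp(x, as.numeric(y), partition$start, partition$end,
                       as.integer(train) - 1L, as.integer(validation) - 1L,
                       basis$centers, basis$window, basis$win_offset,
                       step, as.integer(max_iter))
  structure(list(coef = res$coef, log = res$log, n_iter = res$n_iter,
                 basis = basis, step = step,
                 train = train, validation = validation),
            class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  acc <- sum(x$log$accepted)
  cat("Boosting run: ", x$n_iter, " iterations (", acc, " accepted), ",
      sum(abs(x$coef) > 0), " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Fit a multivariate temporal response function by boosting
#'
#' Estimates, independently for every response channel ("source"), a set
#' of linear kernels — one per predictor — whose summed convolutions with
#' the predictor time series model the continuous response. Kernels live
#' on a basis of 50 ms Hamming windows over lags from -100 to 1000 ms and
#' are estimated by steepest l1 coordinate descent (boosting) with
#' validation-based early stopping and per-predictor freezing.
#'
#' All predictors and the response are standardized (centered, scaled to
#' unit mean absolute value) before estimation. The data are split along
#' time into `k` contiguous, equal-length segments. For each test
#' segment, each of the remaining `k - 1` segments serves once as the
#' validation segment while the other `k - 2` train, giving `k - 1`
#' training runs whose mTRFs are averaged to predict the held-out test
#' segment. Concatenating the held-out predictions yields the
#' cross-validated model quality index \eqn{1 - \ell_1(res)/\ell_1(y)}
#' per source. The fit is deterministic given its inputs.
#'
#' @param x predictors: a named list of [predictor_track()]s or a numeric
#'   matrix (time x predictor).
#' @param y response: numeric vector, or matrix (time x source) for
#'   multiple sources.
#' @param fs sampling rate in Hz (required if `x` is a bare matrix).
#' @param basis a [make_basis()] object; default is the standard basis at
#'   `fs`.
#' @param k number of cross-validation segments (default 4).
#' @param step boosting step size on the standardized scale.
#' @param seed recorded for provenance; the estimator itself is
#'   deterministic.
#' @param max_iter safety cap per training run.
#' @return An object of class `"mtrf"` with methods `print`, `summary`,
#'   `coef` (lag-domain kernels), `predict`, `fitted`, `residuals`,
#'   `plot`, and `simulate`. Fields include `quality` (per-source model
#'   quality index), `l1_resid`, `l1_y`, `coef` (basis-domain coefficient
#'   array, predictor x basis x source, averaged over test segments), and
#'   `coef_by_test` (per test segment).
#' @examples
#' \donttest{
#' set.seed(1)
#' fs <- 50
#' n <- 3000
#' x <- matrix(rbinom(2 * n, 1, 0.05), n, 2)
#' b <- make_basis(0, 300, 60, 20, fs)
#' h <- sin(seq(0, pi, length.out = 8))
#' y <- stats::filter(x[, 1], c(rep(0, 3), h), sides = 1)
#' y[is.na(y)] <- 0
#' fit <- mtrf(x, y + rnorm(n, sd = 0.1), fs = fs, basis = b)
#' fit$quality
#' }
#' @export
mtrf <- function(x, y, fs = NULL, basis = NULL, k = 4L, step = 0.005,
                 seed = NULL, max_iter = 100000L) {
  px <- as_predictor_matrix(x, fs)
  fs <- px$fs
  if (is.null(fs)) stop("`fs` is required when `x` is a plain matrix")
  if (is.null(basis)) basis <- make_basis(fs = fs)
  if (!isTRUE(all.equal(basis$fs, fs)))
    stop("basis sampling rate does not match the data")
  y <- as.matrix(y)
  n <- nrow(px$x)
  if (nrow(y) != n) stop("predictors and response differ in length")
  n_src <- ncol(y)
  p <- ncol(px$x)
  lag_len <- basis$lag_max - basis$lag_min + 1L
  if (n < k * lag_len * 10L)
    stop("response too short: need at least k * 10 * lag-window samples (",
         k * lag_len * 10L, "), got ", n)

  xs <- apply(px$x, 2L, standardize, simplify = FALSE)
  X <- vapply(xs, `[[`, numeric(n), "values")
  x_center <- vapply(xs, `[[`, 0, "center")
  x_scale <- vapply(xs, `[[`, 0, "scale")
  part <- cv_partition(n, k)

  nb <- length(basis$centers)
  coef_by_test <- array(0, c(p, nb, k, n_src))
  yhat <- matrix(0, n, n_src)
  quality <- l1r <- l1y <- numeric(n_src)
  y_center <- y_scale <- numeric(n_src)
  freeze_logs <- vector("list", n_src)
  for (s in seq_len(n_src)) {
    ys <- standardize(y[, s])
    y_center[s] <- ys$center
    y_scale[s] <- ys$scale
    logs <- list()
    for (test in seq_len(k)) {
      rots <- cv_rotations(k, test)
      cf <- matrix(0, p, nb)
      for (r in rots) {
        bf <- boost_fit(X, ys$values, part, r$train, r$val, basis,
                        step = step, max_iter = max_iter)
        cf <- cf + bf$coef
        fl <- bf$log[bf$log$accepted == 0, c("iter", "predictor"),
                     drop = FALSE]
        if (nrow(fl))
          logs[[length(logs) + 1L]] <-
            cbind(test = test, validation = r$val, fl)
      }
      cf <- cf / length(rots)
      coef_by_test[, , test, s] <- cf
      ph <- predict_mtrf_cpp(X, cf, basis$centers, basis$window,
                             basis$win_offset,
                             part$start[test], part$end[test])
      sel <- (part$start[test] + 1L):part$end[test]
      yhat[sel, s] <- ph[sel]
    }
    l1r[s] <- sum(abs(ys$values - yhat[, s]))
    l1y[s] <- sum(abs(ys$values))
    quality[s] <- 1 - l1r[s] / l1y[s]
    freeze_logs[[s]] <- do.call(rbind, logs)
  }
  coef_mean <- array(0, c(p, nb, n_src),
                     dimnames = list(px$names, NULL, colnames(y)))
  for (s in seq_len(n_src))
    coef_mean[, , s] <- apply(coef_by_test[, , , s, drop = FALSE], c(1, 2),
                              mean)
  structure(
    list(coef = coef_mean, coef_by_test = coef_by_test, basis = basis,
         fs = fs, k = k, step = step, seed = seed,
         predictors = px$names, n_sources = n_src, n_time = n,
         partition = part,
         quality = quality, l1_resid = l1r, l1_y = l1y,
         fitted_std = yhat, y = y,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         freeze_log = freeze_logs,
         call = match.call()),
    class = "mtrf")
}

## ---- mtrf methods ----------------------------------------------------------

#' @export
print.mtrf <- function(x, ...) {
  cat("Boosted multivariate TRF\n")
  cat("  predictors: ", paste(x$predictors, collapse = ", "), "\n", sep = "")
  cat("  ", x$n_sources, " source(s), ", x$n_time, " samples @ ", x$fs,
      " Hz, ", x$k, "-fold CV, step ", x$step, "\n", sep = "")
  cat("  cross-validated quality index: ",
      paste(sprintf("%.4f", x$quality), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mtrf <- function(object, ...) {
  ker <- coef(object)
  peak <- apply(abs(ker), c(1, 3), max)
  out <- list(quality = object$quality, l1_resid = object$l1_resid,
              l1_y = object$l1_y, peak_amplitude = peak,
              predictors = object$predictors, k = object$k,
              step = object$step)
  class(out) <- "summary.mtrf"
  out
}

#' @export
print.summary.mtrf <- function(x, ...) {
  cat("Boosted mTRF fit (", x$k, "-fold CV)\n", sep = "")
  cat("Per-source model quality index (1 - l1(res)/l1(y)):\n")
  print(round(x$quality, 4))
  cat("Peak |kernel| per predictor x source (standardized scale):\n")
  print(round(x$peak_amplitude, 4))
  invisible(x)
}

#' Lag-domain kernels of a fitted mTRF
#'
#' @param object an `mtrf` fit.
#' @param domain `"lag"` for kernels over lags (default) or `"basis"` for
#'   raw basis coefficients.
#' @param ... unused.
#' @return Array `predictor x lag x source` (lag domain, with lag times in
#'   ms as dimnames) or `predictor x basis x source`.
#' @export
coef.mtrf <- function(object, domain = c("lag", "basis"), ...) {
  domain <- match.arg(domain)
  if (domain == "basis") return(object$coef)
  B <- basis_matrix(object$basis)
  p <- dim(object$coef)[1L]
  ker <- array(0, c(p, nrow(B), object$n_sources),
               dimnames = list(object$predictors,
                               format(basis_lags_ms(object$basis)),
                               NULL))
  for (s in seq_len(object$n_sources))
    ker[, , s] <- object$coef[, , s] %*% t(B)
  ker
}

#' Predict a response from a fitted mTRF
#'
#' Standardizes `newdata` with the standardization recorded at fit time,
#' convolves it with the fitted kernels (sum over predictors, zero-padded
#' segment-local convolution over the stated lag window), and returns the
#' prediction on the original response scale. The prediction is linear in
#' the predictors.
#'
#' @param object an `mtrf` fit.
#' @param newdata predictors as at fit time (list of tracks or matrix);
#'   default: the training predictors' fitted values are returned.
#' @param sources integer subset of sources (default all).
#' @param ... unused.
#' @return Matrix `time x source` of predicted responses.
#' @export
predict.mtrf <- function(object, newdata = NULL, sources = NULL, ...) {
  if (is.null(sources)) sources <- seq_len(object$n_sources)
  if (is.null(newdata)) {
    out <- object$fitted_std[, sources, drop = FALSE]
    return(sweep(sweep(out, 2L, object$y_scale[sources], "*"),
                 2L, object$y_center[sources], "+"))
  }
  px <- as_predictor_matrix(newdata, object$fs)
  if (ncol(px$x) != length(object$predictors))
    stop("`newdata` must have the same predictors as the fit")
  X <- sweep(sweep(px$x, 2L, object$x_center, "-"),
             2L, object$x_scale, "/")
  n <- nrow(X)
  out <- matrix(0, n, length(sources))
  for (i in seq_along(sources)) {
    s <- sources[i]
    yh <- predict_mtrf_cpp(X, coef_slice(object$coef, s),
                           object$basis$centers, object$basis$window,
                           object$basis$win_offset,
                           0L, as.integer(n))
    out[, i] <- yh * object$y_scale[s] + object$y_center[s]
  }
  out
}

#' @export
fitted.mtrf <- function(object, ...) predict(object)

#' @export
residuals.mtrf <- function(object, ...) {
  object$y - predict(object)
}

#' Plot fitted TRF kernels
#'
#' Draws the lag-domain kernel of every predictor for one source.
#'
#' @param x an `mtrf` fit.
#' @param source source index.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mtrf <- function(x, source = 1L, ...) {
  ker <- coef(x)[, , source, drop = FALSE]
  lags <- basis_lags_ms(x$basis)
  graphics::matplot(lags, t(ker[, , 1L]), type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "kernel (standardized)",
                    main = sprintf("mTRF kernels, source %d", source), ...)
  graphics::abline(v = 0, h = 0, col = "grey70")
  graphics::legend("topright", legend = x$predictors, lty = 1,
                   col = seq_len(nrow(ker)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate responses from a fitted mTRF
#'
#' Residual-bootstrap simulation: the fitted prediction plus residuals
#' resampled with replacement, per source.
#'
#' @param object an `mtrf` fit.
#' @param nsim number of simulated response sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of `time x source` matrices.
#' @export
simulate.mtrf <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fit <- predict(object)
  res <- object$y - fit
  lapply(seq_len(nsim), function(i)
    fit + apply(res, 2L, sample, replace = TRUE))
}

## ---- model comparison ------------------------------------------------------

#' Predictive improvement of a full over a reduced mTRF model
#'
#' Fits the full predictor set and a reduced set (the full set minus the
#' feature(s) under investigation) with an identical partition, basis and
#' step, and returns the per-source increase in cross-validated model
#' quality index — a conservative estimate of the unique contribution of
#' the omitted feature(s).
#'
#' @param x full predictor set (named list of tracks or named matrix).
#' @param y response vector or matrix.
#' @param reduced character vector of predictor names forming the reduced
#'   set; must be a strict subset of the full set's names.
#' @inheritParams mtrf
#' @param ... passed on to [mtrf()].
#' @return An object of class `"mtrf_improvement"`: per-source `delta`
#'   (quality full - quality reduced), plus both fits.
#' @export
mtrf_improvement <- function(x, y, reduced, fs = NULL, basis = NULL,
                             k = 4L, step = 0.005, seed = NULL, ...) {
  px <- as_predictor_matrix(x, fs)
  if (!all(reduced %in% px$names))
    stop("`reduced` must be a subset of the full predictor names")
  full_fit <- mtrf(px$x, y, fs = px$fs, basis = basis, k = k, step = step,
                   seed = seed, ...)
  red_fit <- mtrf(px$x[, reduced, drop = FALSE], y, fs = px$fs,
                  basis = basis, k = k, step = step, seed = seed, ...)
  structure(list(delta = full_fit$quality - red_fit$quality,
                 quality_full = full_fit$quality,
                 quality_reduced = red_fit$quality,
                 full = full_fit, reduced = red_fit,
                 omitted = setdiff(px$names, reduced)),
            class = "mtrf_improvement")
}

#' @export
print.mtrf_improvement <- function(x, ...) {
  cat("mTRF model improvement (omitted: ",
      paste(x$omitted, collapse = ", "), ")\n", sep = "")
  cat("  quality full:    ", paste(sprintf("%.4f", x$quality_full),
                                   collapse = ", "), "\n", sep = "")
  cat("  quality reduced: ", paste(sprintf("%.4f", x$quality_reduced),
                                   collapse = ", "), "\n", sep = "")
  cat("  delta:           ", paste(sprintf("%+.4f", x$delta),
                                   collapse = ", "), "\n", sep = "")
  invisible(x)
}
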