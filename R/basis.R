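#' Hamming-window basis for temporal response functions
#'
#' TRF kernels are parameterized on a basis of Hamming windows of fixed
#' width whose centers tile the lag window at a fixed stride; each
#' coefficient update during boosting moves the kernel by one scaled
#' Hamming bump. Defaults follow the estimation setup used throughout the
#' package: 50 ms wide windows centered at lags from -100 ms up to (but
#' excluding) 1000 ms, one center per 10 ms.
#'
#' @param tmin_ms first basis center (ms; negative lags are anticipatory).
#' @param tmax_ms exclusive upper bound for centers (ms).
#' @param width_ms width of each Hamming window (ms); must span at least
#'   two samples at `fs`.
#' @param stride_ms spacing of centers (ms).
#' @param fs sampling rate in Hz.
#' @return An object of class `"trf_basis"`.
#' @examples
#' b <- make_basis(fs = 100)
#' length(b$centers_ms)  # 110
#' @export
make_basis <- function(tmin_ms = -100, tmax_ms = 1000, width_ms = 50,
                       stride_ms = 10, fs = 100) {
  if (tmin_ms >= tmax_ms) stop("`tmin_ms` must be < `tmax_ms`")
  if (width_ms <= 0 || stride_ms <= 0)
    stop("`width_ms` and `stride_ms` must be > 0")
  L <- round(width_ms / 1000 * fs)
  if (L < 2)
    stop("basis width of ", width_ms,
         " ms spans fewer than 2 samples at fs = ", fs, " Hz")
  n_centers <- floor((tmax_ms - tmin_ms) / stride_ms - 1e-9) + 1L
  centers_ms <- tmin_ms + stride_ms * (seq_len(n_centers) - 1L)
  centers <- as.integer(round(centers_ms / 1000 * fs))
  k <- seq_len(L) - 1L
  window <- 0.54 - 0.46 * cos(2 * pi * k / (L - 1))
  off <- (L - 1L) %/% 2L
  lag_min <- min(centers) - off
  lag_max <- max(centers) + (L - 1L - off)
  structure(list(tmin_ms = tmin_ms, tmax_ms = tmax_ms,
                 width_ms = width_ms, stride_ms = stride_ms, fs = fs,
                 centers_ms = centers_ms, centers = centers,
                 window = window, win_offset = off,
                 lag_min = lag_min, lag_max = lag_max),
            class = "trf_basis")
}

#' @export
print.trf_basis <- function(x, ...) {
  cat("TRF basis: ", length(x$centers), " Hamming windows of ",
      x$width_ms, " ms, centers ", x$tmin_ms, "..",
      x$centers_ms[length(x$centers_ms)], " ms (stride ", x$stride_ms,
      " ms) @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Basis-to-lag transformation matrix
#'
#' @param basis a `trf_basis`.
#' @return Matrix of size `n_lags x n_basis` mapping basis coefficients to
#'   lag-domain kernel samples; row `l` corresponds to lag
#'   `basis$lag_min + l - 1` samples.
#' @export
basis_matrix <- function(basis) {
  stopifnot(inherits(basis, "trf_basis"))
  n_lags <- basis$lag_max - basis$lag_min + 1L
  B <- matrix(0, n_lags, length(basis$centers))
  L <- length(basis$window)
  for (j in seq_along(basis$centers)) {
    lags <- basis$centers[j] - basis$win_offset + seq_len(L) - 1L
    B[lags - basis$lag_min + 1L, j] <- basis$window
  }
  B
}

basis_lags_ms <- function(basis) {
  (basis$lag_min:basis$lag_max) / basis$fs * 1000
}
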