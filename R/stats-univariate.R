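## one-sample t per column with a small-variance guard: a zero-variance
## source gets an (effectively infinite) finite t instead of NaN
guarded_t <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  se <- pmax(se, 1e-12)
  m / se
}

## sign-flip matrix: exhaustive when feasible, else seeded random flips
sign_flips <- function(n, n_perm, seed = NULL, exhaustive_limit = 4096L) {
  if (2^n <= exhaustive_limit) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(S) <- NULL
    attr(S, "exhaustive") <- TRUE
    return(S)
  }
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n_perm, n)
  attr(S, "exhaustive") <- FALSE
  S
}

#' Mass-univariate one-sample test with TFCE and sign-flip permutation
#'
#' Tests, per source, whether the group mean of per-subject maps differs
#' from zero. Each subject's map is Gaussian-smoothed, a one-sample t is
#' computed per source, and the t map is enhanced with TFCE. The
#' family-wise null distribution is built by flipping the sign of whole
#' subjects (exhaustively when there are at most `2^n <= 4096` flips,
#' otherwise `n_perm` seeded random flips) and recording the maximum
#' absolute enhanced value; per-source p-values are the proportion of the
#' null at or above each source's enhancement. The summary reports `tmax`,
#' the t value at the most strongly enhanced source (the largest cluster),
#' with its p-value.
#'
#' @param maps a [group_dataset()] or a subjects x sources matrix.
#' @param space required if `maps` is a bare matrix.
#' @param sigma Gaussian smoothing width (coordinate units); 0 disables.
#' @param E,H,dh TFCE parameters, see [tfce()].
#' @param n_perm number of random sign flips when exhaustive enumeration
#'   is infeasible.
#' @param seed RNG seed for random flips.
#' @param exhaustive_limit enumerate all `2^n` sign flips when that count
#'   does not exceed this (default 4096).
#' @return An object of class `"tfce_test"`: per-source `t`, `enhanced`,
#'   `p`, the permutation `null_max` distribution, `tmax` and `p_cluster`.
#' @export
mass_univariate_onesample <- function(maps, space = NULL, sigma = 1,
                                      E = 0.5, H = 2, dh = 0.1,
                                      n_perm = 10000L, seed = NULL,
                                      exhaustive_limit = 4096L) {
  if (inherits(maps, "group_dataset")) {
    space <- maps$space
    maps <- maps$maps
  }
  stopifnot(inherits(space, "source_space"))
  X <- as.matrix(maps)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 subjects")
  X <- smooth_map(X, space, sigma)
  tmap <- guarded_t(X)
  enh <- tfce(tmap, space, E, H, dh)

  S <- sign_flips(n, n_perm, seed, exhaustive_limit)
  m_perm <- (S %*% X) / n
  ssq <- colSums(X^2)
  v_perm <- sweep(-n * m_perm^2, 2L, ssq, "+") / (n - 1)
  v_perm[v_perm < 0] <- 0
  t_perm <- m_perm / pmax(sqrt(sweep(v_perm, 2L, n, "/")), 1e-12)
  null_max <- tfce_max_batch_cpp(t_perm, space$edges[, 1L] - 1L,
                                 space$edges[, 2L] - 1L, E, H, dh)
  exhaustive <- isTRUE(attr(S, "exhaustive"))
  p <- vapply(abs(enh), function(e) perm_p(e, null_max, exhaustive), 0)
  imax <- which.max(abs(enh))
  structure(list(t = tmap, enhanced = enh, p = p, null_max = null_max,
                 tmax = tmap[imax], p_cluster = p[imax],
                 peak_source = imax,
                 n_perm = length(null_max), exhaustive = exhaustive,
                 sigma = sigma, E = E, H = H, dh = dh),
            class = "tfce_test")
}

perm_p <- function(obs, null_max, exhaustive) {
  if (exhaustive) mean(null_max >= obs - 1e-12)
  else (1 + sum(null_max >= obs - 1e-12)) / (1 + length(null_max))
}

#' @export
print.tfce_test <- function(x, ...) {
  cat("Mass-univariate TFCE permutation test\n")
  cat("  ", length(x$t), " sources, ", x$n_perm,
      if (x$exhaustive) " exhaustive sign flips" else " random permutations",
      "\n", sep = "")
  cat(sprintf("  tmax = %.3f at source %d, p = %.4g\n", x$tmax,
              x$peak_source, x$p_cluster))
  cat("  sources with p < 0.05: ", sum(x$p < 0.05), "\n", sep = "")
  invisible(x)
}

#' Hemispheric paired test via left-right mapping
#'
#' Maps each subject's right-hemisphere values onto the left hemisphere
#' through the source space pairing, forms per-subject left-minus-right
#' difference maps, and runs the one-sample TFCE machinery
#' ([mass_univariate_onesample()]) on the differences over the
#' left-hemisphere subgraph. A positive `tmax` therefore indicates
#' stronger left-hemisphere values.
#'
#' @inheritParams mass_univariate_onesample
#' @return A `"tfce_test"` over left-hemisphere sources, with the
#'   left-source indices in `$sources`.
#' @export
hemispheric_paired_test <- function(maps, space = NULL, sigma = 1,
                                    E = 0.5, H = 2, dh = 0.1,
                                    n_perm = 10000L, seed = NULL) {
  if (inherits(maps, "group_dataset")) {
    space <- maps$space
    maps <- maps$maps
  }
  stopifnot(inherits(space, "source_space"))
  if (is.null(space$pairing))
    stop("hemispheric test requires a left-right pairing in the space")
  left <- which(space$hemisphere == "L")
  diffs <- maps[, left, drop = FALSE] -
    maps[, space$pairing[left], drop = FALSE]
  lspace <- subset_space(space, space$hemisphere == "L")
  out <- mass_univariate_onesample(diffs, lspace, sigma = sigma, E = E,
                                   H = H, dh = dh, n_perm = n_perm,
                                   seed = seed)
  out$sources <- left
  out
}
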