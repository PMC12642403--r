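#' Spatiotemporal cluster permutation test on TRFs
#'
#' Compares per-subject TRF kernels between two groups at every (source,
#' lag) point with an independent two-sample t-test (pooled variance),
#' forms clusters of points exceeding the cluster-forming threshold
#' (|t| > t at `alpha`, two-sided) that are connected through the spatial
#' adjacency graph and adjacent lags, and evaluates each cluster's summed
#' t (its mass) against a label-permutation null of the maximum absolute
#' cluster mass. Reported per cluster: mass, p, the lag span, and the
#' spatial extent as a percentage of the sources in the space — the
#' measure used to judge whether a group difference occupies at least
#' e.g. 2% or 5% of an ROI.
#'
#' @param trfs numeric array `subject x source x lag` of kernels on a
#'   shared grid.
#' @param labels per-subject group labels; exactly two levels, each with
#'   at least 2 subjects.
#' @param space a [source_space()] providing the spatial adjacency.
#' @param alpha cluster-forming significance level (two-sided).
#' @param n_perm number of random label permutations.
#' @param seed RNG seed for the permutations.
#' @param lags_ms optional lag times (ms) for reporting cluster spans.
#' @return An object of class `"cluster_test"`: `t` (source x lag map),
#'   `clusters` (data frame: mass, p, lag/source extents), `labels`
#'   (cluster id per point), `null_max`.
#' @export
trf_cluster_test <- function(trfs, labels, space, alpha = 0.05,
                             n_perm = 1000L, seed = NULL,
                             lags_ms = NULL) {
  stopifnot(inherits(space, "source_space"), length(dim(trfs)) == 3L)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("cluster test requires exactly two groups")
  if (any(table(labels) < 2L))
    stop("need at least 2 subjects per group")
  ns <- dim(trfs)[2L]
  nt <- dim(trfs)[3L]
  if (ns != space$n) stop("source dimension does not match the space")
  n <- dim(trfs)[1L]
  X <- matrix(trfs, n, ns * nt)  # subjects x (source,lag) cells
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  df <- n1 + n2 - 2L
  thr <- stats::qt(1 - alpha / 2, df)
  e0 <- space$edges[, 1L] - 1L
  e1 <- space$edges[, 2L] - 1L

  two_sample_t <- function(sel1) {
    m1 <- colMeans(X[sel1, , drop = FALSE])
    m2 <- colMeans(X[!sel1, , drop = FALSE])
    q1 <- colSums(X[sel1, , drop = FALSE]^2) - n1 * m1^2
    q2 <- colSums(X[!sel1, , drop = FALSE]^2) - n2 * m2^2
    sp <- sqrt(pmax(q1 + q2, 0) / df * (1 / n1 + 1 / n2))
    (m1 - m2) / pmax(sp, 1e-12)
  }

  tmap <- matrix(two_sample_t(g1), ns, nt)
  obs <- label_clusters_cpp(tmap, thr, e0, e1)

  if (!is.null(seed)) set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    tm <- matrix(two_sample_t(g1[perm]), ns, nt)
    null_max[b] <- max_cluster_mass_cpp(tm, thr, e0, e1)
  }

  mass <- obs$mass
  labs <- obs$labels
  if (length(mass)) {
    p <- vapply(abs(mass), function(m)
      (1 + sum(null_max >= m - 1e-12)) / (1 + n_perm), 0)
    info <- lapply(seq_along(mass), function(id) {
      w <- which(labs == id, arr.ind = TRUE)
      lag_rng <- range(w[, 2L])
      data.frame(cluster = id, mass = mass[id], p = p[id],
                 n_points = nrow(w),
                 n_sources = length(unique(w[, 1L])),
                 extent_pct = 100 * length(unique(w[, 1L])) / ns,
                 lag_from = if (is.null(lags_ms)) lag_rng[1L]
                            else lags_ms[lag_rng[1L]],
                 lag_to = if (is.null(lags_ms)) lag_rng[2L]
                          else lags_ms[lag_rng[2L]])
    })
    clusters <- do.call(rbind, info)
    clusters <- clusters[order(clusters$p, -abs(clusters$mass)), ]
  } else {
    clusters <- data.frame(cluster = integer(0), mass = numeric(0),
                           p = numeric(0), n_points = integer(0),
                           n_sources = integer(0), extent_pct = numeric(0),
                           lag_from = numeric(0), lag_to = numeric(0))
  }
  structure(list(t = tmap, clusters = clusters, labels = labs,
                 null_max = null_max, threshold = thr, alpha = alpha,
                 groups = levels(labels), n_perm = n_perm),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Spatiotemporal cluster permutation test (",
      paste(x$groups, collapse = " vs "), ")\n", sep = "")
  cat("  forming threshold |t| > ", round(x$threshold, 3), ", ",
      x$n_perm, " permutations\n", sep = "")
  if (nrow(x$clusters) == 0L) cat("  no clusters formed\n")
  else print(utils::head(x$clusters, 10L), row.names = FALSE)
  invisible(x)
}

#' Peak analysis of spatially averaged TRFs
#'
#' Finds, per subject, the local extrema of a spatially averaged kernel
#' whose absolute amplitude exceeds a prominence floor (a fraction of the
#' subject's maximum absolute kernel value), matches peaks across
#' subjects by their ordinal position within sign (first positive peak,
#' second positive peak, first negative peak, ...), and tests amplitude
#' and latency of each matched peak between two groups with independent
#' t-tests.
#'
#' @param kernels numeric matrix `subject x lag` of spatially averaged
#'   kernels on a common lag grid.
#' @param labels per-subject group labels (two levels) or `NULL` to only
#'   extract peaks.
#' @param lags_ms lag times in ms (default: sample index).
#' @param prominence prominence floor as a fraction of each subject's
#'   maximum absolute amplitude (default 0.1).
#' @return An object of class `"peak_analysis"`: `peaks` (one row per
#'   subject-peak: subject, sign, ordinal, latency, amplitude) and
#'   `tests` (per matched peak: t and p for amplitude and latency
#'   differences; empty without labels).
#' @export
peak_analysis <- function(kernels, labels = NULL, lags_ms = NULL,
                          prominence = 0.1) {
  kernels <- as.matrix(kernels)
  n <- nrow(kernels)
  if (is.null(lags_ms)) lags_ms <- seq_len(ncol(kernels))
  peaks <- list()
  for (s in seq_len(n)) {
    k <- kernels[s, ]
    floor_amp <- prominence * max(abs(k))
    ext <- local_extrema(k)
    keep <- abs(k[ext$index]) >= floor_amp & ext$sign == sign(k[ext$index])
    idx <- ext$index[keep]
    sgn <- ext$sign[keep]
    if (!length(idx)) next
    for (sg in c(1, -1)) {
      ii <- idx[sgn == sg]
      if (!length(ii)) next
      peaks[[length(peaks) + 1L]] <-
        data.frame(subject = s, sign = sg,
                   ordinal = seq_along(ii),
                   latency = lags_ms[ii], amplitude = kernels[s, ii])
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks)
           else data.frame(subject = integer(0), sign = numeric(0),
                           ordinal = integer(0), latency = numeric(0),
                           amplitude = numeric(0))
  tests <- NULL
  if (!is.null(labels) && nrow(peaks)) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L)
      stop("peak tests require exactly two groups")
    peaks$group <- labels[peaks$subject]
    keys <- unique(peaks[, c("sign", "ordinal")])
    rows <- list()
    for (r in seq_len(nrow(keys))) {
      sel <- peaks$sign == keys$sign[r] & peaks$ordinal == keys$ordinal[r]
      pk <- peaks[sel, ]
      if (min(table(factor(pk$group, levels = levels(labels)))) < 2L) next
      safe_t <- function(formula) {
        tryCatch(stats::t.test(formula, data = pk, var.equal = TRUE),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
      }
      ta <- safe_t(amplitude ~ group)  # constant data -> flagged NA
      tl <- safe_t(latency ~ group)
      rows[[length(rows) + 1L]] <-
        data.frame(sign = keys$sign[r], ordinal = keys$ordinal[r],
                   n = nrow(pk),
                   t_amplitude = unname(ta$statistic), p_amplitude = ta$p.value,
                   t_latency = unname(tl$statistic), p_latency = tl$p.value)
    }
    tests <- if (length(rows)) do.call(rbind, rows)
             else data.frame(sign = numeric(0), ordinal = integer(0),
                             n = integer(0), t_amplitude = numeric(0),
                             p_amplitude = numeric(0),
                             t_latency = numeric(0), p_latency = numeric(0))
  }
  structure(list(peaks = peaks, tests = tests, prominence = prominence),
            class = "peak_analysis")
}

## interior local extrema; sign = +1 for maxima, -1 for minima
local_extrema <- function(k) {
  n <- length(k)
  if (n < 3L) return(list(index = integer(0), sign = numeric(0)))
  i <- 2:(n - 1L)
  is_max <- k[i] > k[i - 1L] & k[i] >= k[i + 1L]
  is_min <- k[i] < k[i - 1L] & k[i] <= k[i + 1L]
  idx <- i[is_max | is_min]
  list(index = idx, sign = ifelse(is_max[match(idx, i)], 1, -1))
}

#' @export
print.peak_analysis <- function(x, ...) {
  cat("TRF peak analysis: ", nrow(x$peaks), " peaks (prominence floor ",
      x$prominence, " x max |kernel|)\n", sep = "")
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("Group comparisons per matched peak:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
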