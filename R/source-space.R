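#' Source space: coordinates, adjacency, hemispheres, pairing
#'
#' Describes the geometry shared by all subjects of a study: one entry per
#' virtual source (an abstract response channel), with spatial
#' coordinates, an undirected adjacency graph used by cluster-forming
#' algorithms, a hemisphere label, and optionally a left-right pairing (a
#' bijection between hemispheres) used for hemispheric comparisons.
#'
#' @param coords numeric matrix, one row per source.
#' @param edges two-column integer matrix of undirected edges (1-based
#'   source indices).
#' @param hemisphere character vector of `"L"` / `"R"` per source.
#' @param pairing optional integer vector: `pairing[i]` is the source in
#'   the opposite hemisphere matched to source `i` (must be symmetric).
#' @return An object of class `"source_space"`.
#' @export
source_space <- function(coords, edges, hemisphere,
                         pairing = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge endpoints out of range")
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R")))
    stop("`hemisphere` must be 'L'/'R', one per source")
  if (!is.null(pairing)) {
    pairing <- as.integer(pairing)
    if (length(pairing) != n) stop("`pairing` must have one entry per source")
    ok <- !is.na(pairing)
    if (any(pairing[ok] < 1L | pairing[ok] > n) ||
        any(pairing[pairing[ok]] != which(ok)) ||
        any(hemisphere[pairing[ok]] == hemisphere[ok]))
      stop("`pairing` must be a symmetric bijection between hemispheres")
  }
  structure(list(coords = coords, edges = edges, hemisphere = hemisphere,
                 pairing = pairing, n = n),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat("Source space: ", x$n, " sources (",
      sum(x$hemisphere == "L"), " L / ", sum(x$hemisphere == "R"),
      " R), ", nrow(x$edges), " edges",
      if (!is.null(x$pairing)) ", paired hemispheres" else "", "\n",
      sep = "")
  invisible(x)
}

## restrict a source space to a subset of sources, re-indexing edges
subset_space <- function(space, keep) {
  keep <- which(seq_len(space$n) %in% which(keep))
  idx <- match(seq_len(space$n), keep)  # new index or NA
  e <- space$edges
  e <- e[!is.na(idx[e[, 1L]]) & !is.na(idx[e[, 2L]]), , drop = FALSE]
  e <- cbind(idx[e[, 1L]], idx[e[, 2L]])
  source_space(space$coords[keep, , drop = FALSE], e,
               space$hemisphere[keep])
}

#' Per-subject source maps with group labels
#'
#' Bundles one scalar map per subject (e.g. the improvement in model
#' quality index per source) with the shared source space, a per-subject
#' group label (the subject's native language in the motivating design),
#' and optionally a region-of-interest mask.
#'
#' @param maps numeric matrix, subjects in rows, sources in columns.
#' @param labels per-subject group labels (factor or character).
#' @param space a [source_space()] with as many sources as `maps` has
#'   columns.
#' @param roi optional logical mask over sources.
#' @return An object of class `"group_dataset"`.
#' @export
group_dataset <- function(maps, labels, space, roi = NULL) {
  maps <- as.matrix(maps)
  stopifnot(inherits(space, "source_space"))
  if (ncol(maps) != space$n)
    stop("maps have ", ncol(maps), " sources but the space has ", space$n)
  labels <- as.factor(labels)
  if (length(labels) != nrow(maps))
    stop("need one group label per subject")
  if (!is.null(roi)) {
    roi <- as.logical(roi)
    if (length(roi) != space$n) stop("`roi` must mask every source")
  }
  structure(list(maps = maps, labels = labels, space = space, roi = roi,
                 n_subjects = nrow(maps)),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat("Group dataset: ", x$n_subjects, " subjects x ", x$space$n,
      " sources; groups: ",
      paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gaussian spatial smoothing of a source map
#'
#' Replaces each source's value by a Gaussian-weighted average of all
#' sources, \eqn{v_i' = \sum_j w_{ij} v_j / \sum_j w_{ij}} with
#' \eqn{w_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)} over Euclidean source
#' distances. `sigma = 0` is the identity. Constant maps are unchanged.
#'
#' @param values numeric map (one value per source) or a matrix with
#'   sources in columns (smoothed row-wise).
#' @param space a [source_space()].
#' @param sigma Gaussian width in the units of the source coordinates.
#' @export
smooth_map <- function(values, space, sigma) {
  stopifnot(inherits(space, "source_space"))
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(values)
  D2 <- as.matrix(stats::dist(space$coords))^2
  W <- exp(-D2 / (2 * sigma^2))
  W <- W / rowSums(W)
  if (is.matrix(values)) values %*% t(W) else as.numeric(W %*% values)
}

#' Threshold-free cluster enhancement
#'
#' Enhances a per-source statistic map by integrating, over thresholds
#' `h`, `extent(h)^E * h^H * dh`, where `extent(h)` is the size of the
#' supra-threshold connected component (over the adjacency graph)
#' containing the source. Negative values are enhanced symmetrically on
#' the negated map and returned with negative sign. Thresholds are taken
#' at midpoints `(k - 1/2) dh`.
#'
#' @param stat numeric per-source statistic (e.g. t values); must be
#'   finite.
#' @param space a [source_space()] (its adjacency is used).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step (default 0.1).
#' @return Enhanced map, same sign structure as `stat`.
#' @export
tfce <- function(stat, space, E = 0.5, H = 2, dh = 0.1) {
  stopifnot(inherits(space, "source_space"))
  if (dh <= 0) stop("`dh` must be > 0")
  if (any(!is.finite(stat))) stop("non-finite values in `stat`")
  tfce_cpp(as.numeric(stat), space$edges[, 1L] - 1L,
           space$edges[, 2L] - 1L, E, H, dh)
}
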