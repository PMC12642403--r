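#' Lateralization index
#'
#' \eqn{LI = R / (L + R)}, where `L` and `R` are a feature's predictor
#' strengths (e.g. ROI-mean improvement in model quality) in the left and
#' right hemisphere. 0 means the improvement arises entirely in the left
#' hemisphere, 1 entirely in the right, 0.5 equal improvement, and the
#' index is invariant to a common positive scaling of both strengths.
#' Negative strengths (improvements can be slightly negative) are clipped
#' at zero by default, with a `clipped` attribute flagging where; if both
#' strengths vanish the index is undefined and returned as `NA`.
#'
#' @param L,R numeric vectors of left/right strengths (recycled).
#' @param clip clip negative strengths at zero before forming the index.
#' @return Numeric vector of indices in `[0, 1]` (or `NA`), with
#'   attribute `clipped`.
#' @export
lateralization_index <- function(L, R, clip = TRUE) {
  k <- max(length(L), length(R))
  L <- rep_len(as.numeric(L), k)
  R <- rep_len(as.numeric(R), k)
  clipped <- (L < 0) | (R < 0)
  if (clip) {
    L <- pmax(L, 0)
    R <- pmax(R, 0)
  }
  li <- ifelse(L + R > 0, R / (L + R), NA_real_)
  attr(li, "clipped") <- clipped
  li
}

#' Region-of-interest summary and one-sample test
#'
#' Averages each subject's map over the ROI sources and tests the
#' per-subject means against zero with a two-sided one-sample t-test
#' (df = n - 1). A zero-variance set of subject means cannot be tested
#' and is flagged.
#'
#' @param maps a [group_dataset()] (its `roi` is used unless `roi` is
#'   given) or a subjects x sources matrix.
#' @param roi logical mask over sources; must select at least one.
#' @return A list of class `"roi_summary"`: `subject_means`, and a
#'   one-row data frame `test` with `mean`, `sd`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
roi_summary <- function(maps, roi = NULL) {
  if (inherits(maps, "group_dataset")) {
    if (is.null(roi)) roi <- maps$roi
    maps <- maps$maps
  }
  if (is.null(roi)) roi <- rep(TRUE, ncol(maps))
  roi <- as.logical(roi)
  if (!any(roi)) stop("ROI is empty")
  sm <- rowMeans(as.matrix(maps)[, roi, drop = FALSE])
  n <- length(sm)
  degenerate <- stats::sd(sm) == 0
  if (degenerate) {
    test <- data.frame(mean = mean(sm), sd = 0, t = NA_real_,
                       df = n - 1L, p = NA_real_, degenerate = TRUE)
  } else {
    tt <- stats::t.test(sm)
    test <- data.frame(mean = mean(sm), sd = stats::sd(sm),
                       t = unname(tt$statistic), df = n - 1L,
                       p = tt$p.value, degenerate = FALSE)
  }
  structure(list(subject_means = sm, test = test, n = n),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat("ROI summary over", x$n, "subjects\n")
  print(x$test, row.names = FALSE)
  invisible(x)
}

#' Regression of a per-subject scalar on group (language)
#'
#' Least-squares regression of per-subject values (e.g. ROI-mean
#' improvement, or lateralization index) on the group label with dummy
#' coding against a stated baseline level, reporting per-level estimates,
#' t and p, plus the overall F test of the group factor.
#'
#' @param values numeric per-subject values.
#' @param labels per-subject group labels.
#' @param baseline baseline level; defaults to `"English"` when present,
#'   otherwise the first level.
#' @return An object of class `"language_regression"` with a coefficient
#'   table (`coefficients`), the overall F statistic and p
#'   (`F`, `p_overall`), and the underlying `lm` fit.
#' @export
language_regression <- function(values, labels, baseline = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("need at least 2 groups for a group regression")
  if (any(table(labels) < 2L))
    stop("need at least 2 subjects per group")
  if (is.null(baseline))
    baseline <- if ("English" %in% levels(labels)) "English"
                else levels(labels)[1L]
  labels <- stats::relevel(labels, ref = baseline)
  fit <- stats::lm(values ~ labels)
  sm <- summary(fit)
  cf <- sm$coefficients
  rows <- grep("^labels", rownames(cf))
  tab <- data.frame(level = sub("^labels", "", rownames(cf)[rows]),
                    estimate = cf[rows, 1L], t = cf[rows, 3L],
                    df = fit$df.residual, p = cf[rows, 4L],
                    row.names = NULL)
  fstat <- sm$fstatistic
  p_overall <- stats::pf(fstat[1L], fstat[2L], fstat[3L],
                         lower.tail = FALSE)
  structure(list(coefficients = tab, baseline = baseline,
                 intercept = cf[1L, 1L],
                 F = unname(fstat[1L]), p_overall = unname(p_overall),
                 fit = fit),
            class = "language_regression")
}

#' @export
print.language_regression <- function(x, ...) {
  cat("Group regression (baseline: ", x$baseline, ")\n", sep = "")
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("  overall F = %.3f, p = %.4g\n", x$F, x$p_overall))
  invisible(x)
}

#' Pairwise two-sample t-tests between groups
#'
#' Independent two-sample t-tests (pooled variance) for every pair of
#' group labels present; with two groups the t statistic equals the group
#' contrast of [language_regression()] exactly. Pairs where either group
#' has fewer than 2 subjects are skipped with a warning.
#'
#' @param values numeric per-subject values.
#' @param labels per-subject group labels.
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `estimate` (mean of group1 minus mean of group2), `t`, `df`, `p`.
#' @export
pairwise_language_ttests <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  out <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    a <- values[labels == lv[i]]
    b <- values[labels == lv[j]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("skipping pair ", lv[i], "-", lv[j],
              ": group with fewer than 2 subjects")
      next
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out[[length(out) + 1L]] <-
      data.frame(group1 = lv[i], group2 = lv[j],
                 estimate = mean(a) - mean(b),
                 t = unname(tt$statistic),
                 df = length(a) + length(b) - 2L, p = tt$p.value)
  }
  if (!length(out))
    return(data.frame(group1 = character(0), group2 = character(0),
                      estimate = numeric(0), t = numeric(0),
                      df = integer(0), p = numeric(0)))
  do.call(rbind, out)
}
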