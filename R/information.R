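#' Surprisal and entropy of a discrete distribution
#'
#' Given a probability distribution over outcomes and the outcome actually
#' observed, returns the surprisal of the observation,
#' \eqn{I = -\log p(\mathrm{observed})}, and the Shannon entropy of the
#' distribution, \eqn{H = -\sum_i p_i \log p_i}. These are the two per-event
#' quantities used as linguistic predictors: surprisal of the current unit
#' given its context, and the expected surprisal of the next unit.
#'
#' @param dist numeric vector of probabilities; must sum to 1 (tolerance
#'   `1e-9`). May be named; zero entries are allowed and contribute nothing
#'   to the entropy.
#' @param observed index or name of the observed outcome in `dist`. May be
#'   `NULL` to compute entropy only.
#' @param base logarithm base: 2 for bits, `exp(1)` for nats (default).
#' @return A list with elements `surprisal` (or `NA` if `observed` is
#'   `NULL`) and `entropy`, both nonnegative.
#' @examples
#' information_measures(c(0.5, 0.5), 1, base = 2)  # 1 bit each
#' @export
information_measures <- function(dist, observed = NULL, base = exp(1)) {
  if (!is.numeric(dist) || length(dist) == 0L)
    stop("`dist` must be a non-empty numeric vector")
  if (any(dist < -1e-12) || any(dist > 1 + 1e-9))
    stop("`dist` entries must be probabilities in [0, 1]")
  if (abs(sum(dist) - 1) > 1e-9)
    stop("`dist` must sum to 1 (got ", format(sum(dist)), ")")
  surprisal <- NA_real_
  if (!is.null(observed)) {
    p <- if (is.character(observed)) dist[[observed]] else dist[[observed]]
    if (is.null(p) || is.na(p))
      stop("`observed` outcome not found in `dist`")
    if (p <= 0)
      stop("infinite surprisal: observed outcome has probability 0 (outcome ",
           if (is.character(observed)) observed else as.character(observed),
           ")")
    surprisal <- -log(p, base = base)
  }
  list(surprisal = surprisal, entropy = shannon_entropy(dist, base = base))
}

## Entropy of a (sub)distribution; p need not be pre-pruned of zeros.
shannon_entropy <- function(p, base = exp(1)) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  h <- -sum(p * log(p, base = base))
  max(h, 0)
}
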