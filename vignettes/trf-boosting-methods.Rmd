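---
title: "Methods: boosted temporal response functions for speech prediction signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted temporal response functions for speech prediction signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
```

This vignette documents the models, estimators and numerical choices
implemented in `speechtrf`, in the spirit of a methods section: what is
computed, under which assumptions, which knobs exist, and what the
package's simulation-based validation does and does not establish.

## The generative model

The package assumes a continuous multi-channel neural response
$y_s(t)$ (one series per "source", an abstract channel with a spatial
position and hemisphere label) generated as a sum of convolutions,

$$ y_s(t) = \sum_i (h_{i,s} \ast x_i)(t) + \varepsilon_s(t), $$

where $x_i$ are predictor time series derived from the speech stimulus and
$h_{i,s}$ are the temporal response functions (TRFs) over lags $-100$ to
$1000$ ms (negative lags admit anticipatory responses). Estimating the
$h_{i,s}$ jointly for all predictors — the multivariate TRF (mTRF) — and
comparing models with and without a given predictor measures that
predictor's unique contribution to the response.

## Linguistic predictors

Predictors are built from a forced-alignment-style event table (one row
per phoneme: onset, word, phoneme, word-initial flag). Impulse predictors
place a value at the sample nearest the event onset (ties round to the
earlier sample; coincident impulses sum). Word onsets and non-initial
phoneme onsets go into two separate unit-impulse tracks so that the two
are not collinear.

Three context models assign each phoneme event a probability, from which
surprisal $I = -\log p(\mathrm{phoneme}\mid\mathrm{context})$ and
entropies are derived:

* **Sublexical**: a phoneme n-gram (order 5 by default) gives
  $p(\mathrm{ph}_k \mid \mathrm{ph}_{k-4..k-1})$. Phoneme entropy is the
  entropy of the predicted next-phoneme distribution given the context
  ending at the current phoneme — the average expected surprisal of the
  following phoneme. By default the context crosses word boundaries (the
  conditioning set is simply "the phonemes heard", with a padding symbol
  at the utterance start); a flag restricts contexts to word-internal
  histories instead, since both readings are defensible.
* **Lexical**: an incremental cohort model. At word onset the cohort
  holds the whole lexicon weighted by word frequency; each phoneme sets
  the probability of inconsistent candidates to zero and renormalizes.
  The probability assigned to an incoming phoneme is the total mass of
  candidates that continue with it (the probability of every possible
  word completion). Cohort entropy is the entropy of the candidate-word
  distribution after the update; phoneme entropy is the entropy of the
  next-phoneme distribution the surviving cohort implies (normalized over
  candidates that still have a continuation — completed words predict
  nothing further).
* **Sentence**: the same cohort machinery, but the prior is the word's
  probability under a word n-gram given the preceding four words, so that
  sentence-level constraint sharpens or flattens the cohort.

Numerical conventions, chosen once:

* Entropy is the standard nonnegative $-\sum p \log p$; it cannot be
  negative if it is to mean expected surprisal.
* All information values use one configurable logarithm base, natural log
  by default. Because predictors are standardized before estimation, the
  base only rescales a predictor and cannot change any downstream fit;
  tests that quote values in bits pass base 2 explicitly.
* Out-of-cohort input (a phoneme eliminating every candidate, as happens
  with noisy alignments): the model degrades, for the rest of that word,
  to a flagged uniform next-phoneme distribution over the inventory, with
  cohort entropy defined as zero. This keeps tracks defined without
  inventing probability mass for any specific word.

The n-gram estimator is interpolated absolute discounting with a
configurable discount $d$, bottoming out at a uniform distribution over
the vocabulary; $d = 0$ reproduces maximum-likelihood count ratios
exactly, which is what the count-oracle tests exploit. Models are stored
in backoff form (log10 probability per seen n-gram, log10 backoff weight
per context), so ARPA files round-trip losslessly and externally trained
models can be dropped in.

Acoustic predictors use a bank of 8 fourth-order gammatone filters with
log-spaced center frequencies between 10 and 5000 Hz; per band, the
quadrature magnitude envelope is block-averaged down to the analysis rate
(preserving nonnegativity) and an onset track is its half-wave-rectified
first difference.

## Boosting estimator

Kernels are parameterized on a basis of 50 ms wide Hamming windows whose
centers tile $[-100, 1000)$ ms at a 10 ms stride (110 elements at the
default 100 Hz analysis rate, i.e. one center per sample). Every
predictor and the response are standardized by centering and dividing by
the mean absolute value, so one step size is meaningful across
predictors. The default analysis rate of 100 Hz is an order of magnitude
above the 1–10 Hz band the simulated noise occupies; both are
configurable.

Estimation is fourfold cross-validated: the time axis is split into four
contiguous equal segments (an indivisible remainder joins the last). For
each test segment there are three training runs, each of the remaining
segments serving as the validation segment once while the other two
train; the three mTRFs are averaged to predict the held-out segment.
One training run is steepest l1 coordinate descent with early stopping:

1. Every unfrozen (predictor, basis element) coordinate is probed with
   $\pm\delta$; the change with the maximum l1 error reduction on the
   training segments is applied. Ties resolve to the lowest predictor
   index, then the earliest lag, then the positive sign.
2. If the applied change increases the l1 error on the validation
   segment, it is reverted and the responsible predictor's whole TRF is
   frozen.
3. Training continues until the whole mTRF is frozen; a full sweep in
   which no coordinate reduces training error freezes everything that
   remains (at the first iteration this returns a valid all-zero fit).

The step is $\delta = 0.005$ on the standardized scale, fixed during a
run — small enough that freezing is stable, large enough that runs finish
in hundreds of iterations at the package's default scales. Convolutions
are segment-local with zero padding, and errors are evaluated only on
within-segment samples, so contiguous segments never leak into each
other. The error of a training step is always evaluated on the union of
the two training segments' samples (equivalent to averaging for
equal-length segments).

The implementation point worth documenting: probing every coordinate
exhaustively each iteration is wasteful, so the selection uses an exact
pruning scheme. For a coordinate with convolved pattern $z$ the error
change of a $+\delta$ step obeys
$\Delta \ge -\delta \sum_t \mathrm{sign}(r_t)\, z_t$ (and symmetrically
for $-\delta$), with equality wherever $|r_t| \ge \delta |z_t|$.
Candidates are scanned in ascending order of this lower bound and the
exact $\Delta$ is evaluated only until the bound exceeds the best exact
change found; the sign correlation is maintained incrementally under
residual sign flips and refreshed periodically. The selected coordinate —
including all tie-breaks — is identical to the exhaustive sweep's, which
is also how it is validated; only the work to find it changes. The
estimator is fully deterministic: identical inputs give bit-identical
coefficients.

Model fit is summarized by the quality index
$q = 1 - \ell_1(\mathrm{residuals})/\ell_1(y)$ over the concatenated
held-out predictions: $1$ for a perfect prediction, $0$ for the null
prediction. The unique contribution of a feature is
$\Delta q = q_\mathrm{full} - q_\mathrm{reduced}$, with the reduced model
fitted under an identical partition, basis and step — a conservative
estimate, since shared variance stays with the reduced model.

## Group statistics

Per-subject improvement maps are spatially smoothed with normalized
Gaussian weights over source distances ($\sigma$ = one inter-source
spacing on the synthetic grids by default; $\sigma = 0$ disables).
Mass-univariate one-sample t-tests are enhanced with TFCE,

$$ \mathrm{enh}(s) = \sum_h \mathrm{extent}_h(s)^E \, h^H \, \mathrm{d}h,
   \qquad E = 0.5,\; H = 2,\; \mathrm{d}h = 0.1, $$

where $\mathrm{extent}_h(s)$ is the size of the supra-threshold connected
component containing $s$; negative values are enhanced symmetrically on
the negated map. Thresholds sit at midpoints $(k - \tfrac12)\mathrm{d}h$,
which integrates the $h^H$ factor nearly exactly (the isolated-source
closed form $\int_0^2 h^2\,\mathrm{d}h = 8/3$ is matched to well under 1%
even at $\mathrm{d}h = 0.1$). The threshold count is capped at 2000 —
beyond that $\mathrm{d}h$ is coarsened — so that the small-variance
guard, which maps zero-variance sources to astronomically large t values
rather than NaN, cannot produce an unbounded loop; maps with ordinary t
values never reach the cap.

Family-wise inference uses the maximum-statistic permutation principle:
subject sign flips for one-sample tests (exhaustive when $2^n \le 4096$,
otherwise 10,000 seeded random flips) and group-label permutations for
two-sample tests. Hemispheric comparisons map the right hemisphere onto
the left through the source pairing, form per-subject left-minus-right
differences, and reuse the one-sample machinery. The lateralization
index $LI = R/(L+R)$ is reported per subject and feature; since small
negative improvements occur, strengths are clipped at zero (flagged) so
$LI$ stays in $[0,1]$, and $LI$ is undefined (NA) when both strengths
vanish.

ROI analyses average each subject's map over the mask and use two-sided
one-sample t-tests; group comparisons regress the per-subject means on
the group factor (dummy coding, stated baseline level) and follow up with
pooled-variance pairwise t-tests — with two groups the regression
contrast and the pairwise t agree exactly, up to the sign convention of
the contrast direction. No correction is applied across features or
hemispheres beyond the TFCE/cluster family-wise control, matching
per-feature reporting practice.

The cluster permutation test on the TRFs themselves thresholds the
pointwise two-sample t map at the two-sided $\alpha = 0.05$ quantile,
labels connected components across space (adjacency graph) and time
(adjacent lags), and compares each cluster's summed t against the
permutation null of the maximum absolute cluster mass. Clusters are
reported with their lag span and spatial extent as a percentage of the
sources, the quantity used to judge whether a difference involves at
least 2% or 5% of an ROI. Peak analysis extracts local extrema of
spatially averaged kernels above a prominence floor (10% of the
subject's maximum absolute amplitude by default — "peak" needs an
explicit floor to be well defined), matches them across subjects by
ordinal position within sign, and compares amplitude and latency between
groups with independent t-tests; zero-variance comparisons are flagged
NA rather than fabricated.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, determined
entirely by a specification and a master seed: a Zipf-frequency lexicon
with guaranteed shared-prefix pairs (so cohorts are nontrivial), a
Markov word sequence laid out with gamma-distributed phoneme durations
(mean 80 ms, shape 8 — a regular but jittered speech rate), ground-truth
kernels as sums of basis bumps (an early positive peak near 80 ms and a
later negative peak near 350 ms per predictor by default, staggered
across predictors, with log-normal per-source amplitude jitter), and
responses as the forward convolution plus 1/f noise band-limited to
1–10 Hz at a stated variance SNR. Group structure enters as per-group,
optionally hemisphere-specific, kernel multipliers; subjects share the
stimulus and kernels and differ in noise — mimicking a design where all
participants hear the same audiobook.

Default study scale is deliberately reduced relative to a real
experiment: minutes of stimulus rather than an hour, tens of sources
rather than thousands of dipoles. The validation suite uses, and the
methods were sized for: ~5 minutes at 100 Hz with 4 sources for
noiseless kernel recovery; ~2 minutes with one source and SNR 1 across
20 seeds for the informative-versus-sham improvement contrast; a
20-source grid with 12 subjects and 500 null replications for
calibration of the TFCE, cluster and regression tests; and a three-group
study of 6 subjects per group, 4 sources, ~2 minutes at SNR 1 for the
end-to-end protocol. These scales establish correctness of the
machinery — oracle equivalence, calibration, recovery, determinism — on
data satisfying the generative model. They do not establish robustness
to what real recordings add: correlated noise across sources, model
misspecification (responses not in the basis span, nonlinearities),
predictor collinearity at realistic strengths, alignment errors beyond
the out-of-cohort fallback, or subject-level kernel variability beyond
amplitude scaling.

## Known limitations

* Boosting is the only estimator; no ridge/reverse-correlation variant.
* The cohort model assumes one transcription per word; pronunciation
  variants must be encoded as separate entries.
* Gaussian smoothing uses Euclidean distance between source coordinates,
  not geodesic cortical distance.
* The left-right pairing must be supplied (or comes from the synthetic
  grid); no surface morphing is performed.
* Track containers serialize as delimited text, sized for the package's
  simulation scales rather than hour-long multi-channel recordings.
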