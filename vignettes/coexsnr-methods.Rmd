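---
title: "Scoring expression studies and samples by co-expression consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring expression studies and samples by co-expression consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexsnr)
```

## The model

Gene co-expression is reproducible: across platforms and tissue
collections, many gene pairs are correlated in study after study. This
regularity can serve as an expectation against which any one study is
judged. `coexsnr` estimates the expected structure as the element-wise
median $\hat z$ of Fisher-transformed gene–gene correlation matrices
$z^{s}_{ij} = \operatorname{atanh}(c^{s}_{ij})$ over a compendium of
studies, and scores a study by the Pearson correlation

$$q_s = \operatorname{corr}\bigl(z^{s},\ \hat z\bigr)$$

over the off-diagonal gene pairs defined in both matrices (each unordered
pair counted once). A study full of biological signal reproduces the
expected co-expression and scores high; a study dominated by technical
noise decorrelates from it and scores near zero. We call $q_s$ a
signal-to-noise ratio (SNR) because that is what it tracks, although it is
operationally a correlation of correlations.

The Fisher transform is used for its variance-stabilizing property: for
approximately normal data, $z$ estimated from $n$ samples is normal with
sampling variance $v = 1/(n-3)$, independent of the true correlation. That
gives a clean account of how the score depends on study size. Sampling
error inflates the spread of $z^s$ without adding covariance with
$\hat z$, attenuating $q_s$ in small studies. Writing $\sigma_s$ for the
observed spread of the study's $z$ values, the spread attributable to
biology is $\sigma_s^2 - v$, and the correlation an infinitely large study
would attain is estimated by the classical disattenuation

$$q_s^{\infty} = \frac{q_s}{\sqrt{1 - v/\sigma_s^2}},$$

treating the reference as error-free — a median over many studies, its
sampling error is negligible next to one study's. The estimate is clamped
to $[-1, 1]$. When $\sigma_s^2 \le v$ the observed spread is fully
explained by sampling error; the disattenuated score is then undefined and
returned as `NA` with a warning rather than extrapolated.

### Sample scores

A sample is scored by what its removal does to its study:
$\Delta_i = q(s) - q(s \setminus i)$. Two implementation points matter.

First, the comparison uses a *modified* score in which the denominator
keeps the full study's spread $\sigma_s$ rather than each leave-one-out
study's own spread: a grossly aberrant sample can inflate $\sigma_s$ more
than it perturbs the cross-product, and letting the denominator move with
the removal would let such a sample hide. With the denominator fixed, the
modified score of the full study coincides with $q_s$ exactly, and
leave-one-out values may legitimately exceed 1.

Second, removal is computed by *downdating*. A sample contributes
additively to every pair's complete-observation count, per-gene sums, sums
of squares and cross-products, so the sufficient statistics of the study
without sample $i$ are a rank-1 update of the full-study statistics. One
leave-one-out z matrix therefore costs $O(p^2)$ instead of $O(p^2 n)$, and
the result is identical (to $\sim 10^{-15}$ in practice; the tests assert
$10^{-8}$) to rebuilding the reduced study from scratch.

Deltas are reported both raw and normalized as
$(\Delta_i - \mathrm{median}\,\Delta) / \mathrm{MAD}(\Delta)$, with the
MAD left unscaled (no 1.4826 consistency constant): the intent is a robust
unit, not a normal-theory standard deviation. Centering makes the sign
semantics exact — positive for samples adding reference-consistent signal,
negative for samples adding noise. If the MAD is zero (conceivable only in
degenerate, near-duplicate studies) the normalized scores are undefined
and returned as `NA` with a warning.

A consequence worth stating plainly: the sample score measures the
biological diversity a sample contributes, not technical cleanliness. A
biologically plausible outlier — one sample of a second tissue type among
many of a first — strengthens its study's co-expression signal and scores
*high*. The acceptance suite checks this on purpose.

## Numerical choices

* **Pairwise-complete correlations.** Missing values are handled per gene
  pair; an entry needs at least 4 complete observations and nonzero
  variance in both genes over the pair's samples, otherwise it is marked
  invalid and excluded from every downstream statistic. Validity is
  tracked explicitly rather than imputed.
* **Zero-variance detection.** Variance numerators are compared against a
  relative floor ($10^{-9}$ of the pair's scale) so that a constant gene
  is detected as such despite floating-point rounding; genes are centered
  by their overall mean before the sufficient statistics are formed to
  reduce cancellation.
* **Clipping.** Correlations are clipped to $\pm(1 - 10^{-12})$ before
  $\operatorname{atanh}$ so degenerate perfect correlations stay finite.
* **Medians.** The reference entry is the plain median over the studies in
  which the entry is valid (midpoint for an even count), and requires a
  quorum of at least half the studies — robustness without discarding
  sparsely measured genes entirely. Since $\operatorname{atanh}$ is
  strictly increasing, taking the median on $r$ or on $z$ is equivalent;
  the package takes it on $z$.
* **Joint masking.** The study score, its $\sigma_s$, and the
  disattenuation all use the same jointly-defined pair set, so the
  correction is internally consistent; at least 100 joint pairs are
  required, below which the overlap is refused as unusable.
* **Spreads** are population standard deviations (divide by the pair
  count), which makes the identity "modified score at the full study
  equals $q_s$" exact rather than approximate.

## Preprocessing defaults

Input tables are put on log2 scale when they appear linear-scale: log2
expression rarely exceeds ~20, so a 99th percentile above 30 triggers
`log2(x+1)` (negatives clipped to 0 first). Normalization is Tukey's
median polish (`stats::medpolish`, eps 0.01, at most 10 sweeps — the
classical defaults); downstream correlation uses the matrix with
per-sample column effects removed and per-gene row effects retained, since
Pearson correlation is invariant to per-gene location anyway (asserted
numerically in the tests). Median decompositions are unique only up to the
sweep tolerance, so residual comparisons are made at that tolerance.
Probes missing in strictly more than 25% of samples are dropped (a probe
at exactly 25% is kept); multiple probes per gene collapse by per-sample
median over non-missing probes; probes mapping to more than one gene are
ambiguous and dropped. Cross-platform panels keep the `k` genes (default
2000) present on the most platforms, ties broken by ascending identifier
for determinism.

## What the simulator emulates — and what it does not

`simulate_compendium()` realizes the shared-structure premise with a
latent-factor model: one global $p \times f$ loading matrix (standard
normal entries), standard normal factor scores per sample, i.i.d. Gaussian
measurement noise per gene, and optional biological classes that shift a
random half of the factor means. Defaults are $p = 200$ genes, $f = 10$
factors, 20 studies of 50 samples, noise SD 1 (noise variance comparable
to the per-gene signal variance from ~10 unit-variance factors — a study
where signal clearly dominates but noise is far from negligible), class
shift 2 (a two-SD separation, typical of distinct tissue classes). All
randomness flows through one explicit integer seed per call; identical
seeds give bit-identical output.

The experiments in the acceptance suite use this generator at the
following sizes, chosen to keep every statistic away from saturation while
running on a single CPU in minutes: leave-one-out exactness on 20 studies
of 30 genes × 15 samples; null calibration on 100 pairs of independent
200-gene studies; disattenuation flatness on one 500-sample study
subsampled at n ∈ {25, 50, 100, 200}, 50 replicates; the noise curve on a
30-sample two-class study over noise SDs {0, 0.5, 1, 2, 4}, 20 replicates;
corrupted-sample detection on 100 studies of 40 samples; the outlier
experiments on pools of ~350 samples per class, 50 replicates.

The generator does *not* emulate platform-specific probe effects, dye
bias, batch structure, heavy-tailed noise, or missingness mechanisms.
Passing tests on it demonstrate that the estimator does what the theory
says under the model's assumptions (shared low-rank structure, Gaussian
noise); they do not certify behavior on any particular real platform.
Correlated technical artifacts — batches that mimic co-expression — are
the known blind spot of any co-expression-based score.

## Design choices that were genuinely open

* **Pooled-variance t-test** for the %DEG validation statistic: the
  classical two-sample "T-test", not Welch. The default threshold is
  0.001, configurable.
* **Naive Bayes posteriors** are Gaussian with a variance floor of
  $10^{-6}$ and *equal* class priors regardless of class sizes
  (uninformative prior); the reported value is the posterior of the
  sample's true class, in a leave-one-out loop.
* **Disattenuation is one-sided**: only the scored study's sampling error
  is corrected, not the reference's (see above).
* **$\sigma_s$ after masking**: the spread entering the disattenuation is
  computed on the jointly defined pairs, not on all of the study's defined
  pairs, keeping numerator and denominator on the same support.
* **Sample deltas are centered before MAD division.** Centering is what
  makes the positive/negative sign semantics hold exactly.
* **No verdict thresholds in the library.** The command-line interface
  prints a warning for studies scoring below 0.05, but nothing is
  filtered: the score is a measurement, and cutoffs belong to the
  analyst.

## Limitations

The score is meaningful only when a study contains real biological
variability: a technically excellent experiment comparing two similar
conditions in replicates has little co-expression signal to exhibit and
will score low without being "bad". Studies need a fair number of diverse
samples (the score requires ≥ 4, sample scoring ≥ 5, and usefulness in
practice starts around a few dozen). The disattenuated score is an
extrapolation and is clamped; the raw score is the safer quantity for
ranking same-size studies. And because the reference is a median over the
compendium, a pathology shared by most of the compendium would be invisible
to it.
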