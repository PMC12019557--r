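---
title: "Consensus annotation of continuous emotion ratings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus annotation of continuous emotion ratings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoconsensus)
```

This vignette documents the statistical model behind `emoconsensus`, the
choices made where the procedure admits more than one reading, and what
the synthetic-data generator does and does not emulate.

## The measurement model

Each film × item combination is assumed to elicit a shared latent response
$s(t)$, sampled at 1 Hz over the film. Rater $i$ reports

$$x_i(t) = \mathrm{clip}_{[0,100]}\!\left(50 + b_i + g_i\,
  \bigl(s(t) + \varepsilon_i(t)\bigr)\right),
  \qquad \varepsilon_i(t) \sim \mathcal{N}(0, \sigma_n^2)\ \text{iid},$$

with rater-specific gain $g_i > 0$ and offset $b_i$: raters agree on the
*shape* of the response but not on how they use the slider. z-scoring each
rater's series removes $g_i$ and $b_i$ exactly (up to clipping), which is
why all agreement computations operate on z-scored data. Under this model
the expected pairwise Pearson correlation between two raters is the
attenuation ratio

$$\rho = \frac{\sigma_s^2}{\sigma_s^2 + \sigma_n^2},$$

so a target agreement $\rho^\ast$ fixes the noise level
$\sigma_n = \sigma_s\sqrt{1/\rho^\ast - 1}$
(`choose_noise_for_agreement()`), and the consensus of $n$ raters has

$$\operatorname{cor}(\bar{x}, s) =
  \frac{1}{\sqrt{1 + \sigma_n^2 / (n\,\sigma_s^2)}},$$

the closed form the test suite checks (≈ 0.894 for $n = 4$,
$\sigma_n = \sigma_s$).

## Normalisation and screens

**z-scoring scope.** A rater's series for one item is normalised using the
pooled mean and *population* SD (divide by $N$) of that rater's films for
that item. Pooling across films preserves between-film level differences,
which the per-film mean-level summaries of the consensus rely on; pooling
is *not* extended across items because items have different poles and
meanings. Pooling across items as well is arguable; the per-item scope is
the package default and the only behaviour exposed by
`zscore_within_rater()`, whose input contract (one rater, one item) makes
the scope explicit.

**Imputation.** Isolated missing samples are replaced by the mean of their
two neighbours, an edge sample by its single neighbour. The two-neighbour
rule does not define behaviour for runs of two or more missing samples, so
those raise an error by default; `fallback = "linear"` interpolates across
the gap and logs the count. Imputation follows z-scoring (the normalisation
statistics simply skip missing samples) and never changes series length;
the original missing mask is preserved on the output.

**Constant and outlier screens.** A series whose non-missing samples have
zero variance is discarded, as is a series with any sample beyond the
|z| = 15 threshold. "Beyond" is read as a *strict* inequality: a sample at
exactly 15 does not trip the screen. Screen order (constant before
outlier) cannot change the survivor set, since a constant series cannot
contain a spike; the suite asserts this order-stability on mixed sets.

## Agreement and the exclusion cascade

Agreement per film × item is the mean of all $\binom{n}{2}$ pairwise
Pearson correlations. The deviance rule — discard a series whose inclusion
reduces mean r by more than 0.20 — is implemented as a *greedy iterated*
cascade: recompute leave-one-out improvements after each removal, remove
the best candidate while its improvement exceeds 0.20, never dropping
below 3 survivors. The single-pass reading is ambiguous when two removals
interact; greedy iteration is determinate, and on small instances (≤ 5
series) it reproduces the terminal state of an exhaustive search over all
admissible removal sequences (checked in the test suite and the acceptance
script). Ties anywhere are broken on rater id (lexicographically last
removed) for determinism; with continuous data ties have probability zero.

Where five annotations exist, the one with the lowest mean correlation to
the others is removed *after* the deviance cascade, matching the stated
order of the procedure. Item gating (remove < 0.15, flag < 0.20) and film
gating (remove < 0.25) are applied, by default, to agreement computed on
cascade survivors; the narrative order of the original procedure can be
read either way, so `run_consensus_pipeline(gate = "before")` exposes the
alternative (gate on pre-cascade agreement, cascade only retained combos).

The consensus is the pointwise mean of survivors and is **not**
re-standardized: its variance, below 1 by noise averaging, carries
information about agreement, and re-scaling would destroy the mean-level
differences between films. Combinations that cannot reach three survivors
are emitted to a rejects table, never silently dropped, and the ledger
identity `available = survivors + Σ removals` is asserted on every run
(`ledger_counts()`, `reconcile_ledger()`).

## Clip validation

Sparse clip ratings are anchored at each clip's temporal midpoint — a
rating summarising a clip is best localised at its centre — linearly
interpolated to the 1 Hz film grid, and extended as constants beyond the
terminal anchors (linear extrapolation would let edge excursions dominate
the correlation). Subject series are z-scored, averaged, and correlated
with the consensus; when lengths differ by one sample (films are not
integer seconds) the pair is truncated with a warning, larger mismatches
are errors.

The simulator's clip readout deserves a note. A clip rating is modelled as
the subject *integrating the same noisy percept* a continuous rater
reports: the rating is the clip mean of $s(t) + \varepsilon(t)$, hence its
noise SD is $\sigma_n / \sqrt{L}$ for a clip of $L$ seconds
(`noise_model = "integrating"`, the default). This is the coherent
single-model choice — continuous rating and clip rating are two readouts
of one percept process — and under it the grand-mean validation
correlation lands within Monte-Carlo error of the grand-mean inter-rater
agreement, reproducing the qualitative equivalence of the two quality
measures. The alternative `"per_rating"` readout (full $\sigma_n$ per
rating) is exposed for sensitivity analyses; it depresses validation by
roughly 0.05 at the default latent timescale.

## Physiological regressors

Raw 1000 Hz traces are conditioned by zero-phase (forward–backward)
4th-order Butterworth filtering with odd-reflection padding (the plain
filter would leak edge transients), decimated to 40 Hz after an
anti-alias low-pass at 16 Hz, then filtered at 8 Hz (cardiac) or 2 Hz
(respiration). Peaks are local maxima exceeding a prominence threshold
(default half the trace SD) with a greedy tallest-first refractory rule
(0.5 s cardiac, 2 s respiration); a manual-edit hook applies add/remove
operations and logs them, mirroring supervised peak correction.

The heartbeat-interval regressor is the median inter-beat interval in a
centred 6 s window (midpoint assignment; empty windows carry the nearest
defined value), and respiratory variance is the variance in a centred 8 s
window, truncated at the record edges. Both are emitted at 1 Hz by default
to align with the annotation grid — the output rate is not fixed by the
procedure, and `out_rate_hz` re-targets it (e.g. `1/1.3` for a 1.3 s
scanner TR). The convolution kernels are the canonical closed forms from
the literature — the Chang–Glover cardiac response function (negated, as
"opposite of the cardiac response function" is read as pointwise negation)
and the Birn respiratory response function — sampled over 40 s and
normalised to unit L1 norm, so convolution is scale-preserving and a unit
impulse is the identity. Regressors are computed on whatever padding the
trace carries and can be trimmed afterwards; padding handling is left to
the caller because run-splitting conventions vary.

## What the generator emulates — and what it does not

Defaults are the study conditions the pipeline is designed for: sixteen
films of 402–1028 s (`default_film_table()`), four raters per film × item
assigned by lists of six items (`build_assignment_grid()`; surplus list
slots give a few items a fifth rater, the source of worst-of-five cases),
a latent signal with Gaussian-kernel smoothing of SD 5 s (slow emotional
dynamics with the closed-form lag-$k$ autocorrelation
$\exp(-k^2/(4\cdot 25))$, convenient for testing), rater gains uniform on
8–12 and biases on ±5 about the scale midpoint 50, clipping to [0, 100],
and a target mean agreement of 0.39. Contamination rates default to the
proportions implied by the study's exclusion ledger (constant 0.001,
outlier 0.017, deviant 0.044 per rater). Outlier raters are generated at
unit effective gain so that a one-sample excursion to the scale end
exceeds |z| = 15 after pooled normalisation (guaranteed when roughly 250+
pooled samples back each spike); deviant raters track an independent
latent draw; constant raters hold their offset.

Not modelled: film content and its autocorrelation structure beyond a
single smoothing scale, rater fatigue or order effects, slow drifts in
scale use within a rater, non-Gaussian noise, and any BOLD signal. Passing
tests therefore demonstrate that the pipeline's operations are correct
under the stated measurement model, not that real raters satisfy that
model; in real data the latent dynamics are slower and more structured,
which tends to make interpolation-based validation easier, not harder.

## Known limitations

* **Deviance screen power.** The leave-one-out improvement statistic for a
  single deviant rater among four has expectation
  $3\rho/6 - 0 = \rho/2$ (the three clean pairs' agreement redistributed
  over six pairs). At the screen's 0.20 threshold this leaves little
  margin: at $\rho = 0.5$ the margin is 0.05, and the statistic's sampling
  SD on a 400–1000 s film with a 5 s-smooth latent is ≈ 0.03–0.05 (the
  autocorrelation shrinks the effective sample size roughly twelvefold),
  so a single deviant is removed in only ~90% of combinations, and at the
  default target agreement of 0.39 the expected improvement ($\approx
  0.195$) sits *below* the threshold — mildly deviant raters are retained
  by design. Two deviants in one four-rater combination mask each other
  entirely (each removal improves the remainder by ≈ $\rho/6$). The screen
  is a coarse instrument for flagrant deviance, not a consistent outlier
  detector; the sensitivity experiments in the acceptance script inject at
  most one deviant per combination for this reason.
* **Clipping attenuation.** The 0–100 bounds attenuate agreement slightly
  (≈ 0.005 at default gains); the calibration targets are expectations
  before clipping.
* **Order ambiguities.** Whether gating preceded the cascade, and whether
  z-scoring pooled items as well as films, are not fully determined by the
  procedure's description; the defaults here (gate after; pool per item)
  are stated above and the first is switchable.

## Problem sizes

The test suite and acceptance script run entirely on simulated data at
sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances: 100 combinations for agreement calibration (SE ≈ 0.007), 200
replicates for the consensus closed form (SE ≈ 0.002), 100 + 100
combinations for cascade sensitivity/specificity, 40 combinations for the
validation grand mean, 8 items × 5 films for the meta-correlation, and 50
instances for the greedy-vs-exhaustive comparison. A full run takes well
under a minute on one core.
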