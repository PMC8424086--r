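---
title: "Quantifying infant general movements: the KC index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant general movements: the KC index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The clinical problem

Spontaneous *general movements* (GMs) of young infants are a sensitive
early window on the developing nervous system. Trained observers classify
them as normal (N) or abnormal, the abnormal patterns being *poor
repertoire* (PR: repetitive movement sequences with low variability) and
*cramped synchronized* (CS: rigid movements in which all body parts
contract and relax almost simultaneously). Expert visual assessment is
accurate but scarce and subjective at the margins. This package implements
an automated, quantitative counterpart built on four limb-worn tri-axial
accelerometers (left/right wrist, left/right ankle), sampled nominally at
150 Hz for 10 minutes.

## The score

Two aspects of the clinical judgement are made quantitative:

**Single-limb movement character.** For each limb, the three axes of
(gravity-removed) acceleration are collapsed onto their first principal
component — the dominant spatial direction of that limb's movement — and
the Pearson kurtosis $m_4/m_2^2$ of the PC1 score distribution is taken.
Kurtosis is 3 for a Gaussian and at least 1 for any distribution. A limb
that moves often, with varied amplitude, produces a filled-in, nearly
Gaussian amplitude distribution; a limb that is mostly still and then
produces a few self-similar bursts yields a heavy-tailed distribution and a
large kurtosis. Kurtosis is invariant to the amplitude scale and (because
PC1 variance is rotation-invariant) to how the sensor was strapped on.

**Inter-limb coordination.** For the upper pair (LW–RW) and lower pair
(LA–RA), the *jerk* — the time-derivative of acceleration, taken as the
Euclidean norm of the per-axis first differences, hence
orientation-invariant — is cross-correlated. Both series are mean-centered
and coefficient-normalized (the lag-0 value is the Pearson correlation);
the statistic is the maximum over lags within ±2 s, tolerating the small
latencies with which near-simultaneous movements co-occur while a bounded
window avoids spurious far-lag maxima.

The six features (4 kurtosis, 2 cross-correlations) are combined with
equal weights after cohort range normalization:

$$\mathrm{KC}_i = 100\left(\sum_{l=1}^{4}
\frac{kur_{i,l}}{\max_l - \min_l} +
\sum_{p=1}^{2}\frac{xcorr_{i,p}}{\max_p - \min_p}\right),$$

where the extrema are taken over all subjects of the cohort. Higher values
indicate abnormal movement: sparse stereotyped limbs raise the kurtosis
terms, whole-body synchrony raises the cross-correlation terms. The default
mode divides by the range *without* subtracting the minimum — the composite
as defined; a `"min_max"` mode mapping each feature onto $[0,1]$ within the
fitting cohort is available via the config. The two differ by one
cohort-wide constant per cohort, so rankings, ROC curves and AUC are
identical; only the numeric cutoff value changes, so a cutoff must always
travel with the normalization (and mode) it was derived under — which is
what `write_normalization()` and the `classify` subcommand enforce.

Cohort dependence is a real property of this construction: adding one
subject can change every score. For prospective use the package supports a
frozen normalization (`classify_subjects()`), under which existing scores
are provably unchanged when a newcomer is scored.

## Pipeline and its tunables

`score_cohort()` runs, per subject:

1. **Synchronization** (`synchronize()`). Each device has its own timer;
   start offsets and actual rates differ at the sub-millisecond scale, and
   every sample carries its device timestamp. All four limbs are linearly
   interpolated onto one uniform grid at `target_rate_hz` (default 150 Hz)
   covering the intersection of the four spans, left-aligned to the latest
   start so no extrapolation occurs. With clock discrepancies below 1 ms
   against a 6.7 ms sample period, linear interpolation error is far below
   the sensor noise floor; the operation is exact at existing knots, hence
   idempotent on already-uniform data. Recordings whose usable overlap is
   shorter than `min_duration_s` (default 600 s, checked with 5% tolerance)
   are rejected — the standard observation is 10 minutes, but the parameter
   is configurable because real sessions are occasionally cut short by the
   infant's behavioral state.
2. **Optional settling trim** (`trim_settling()`, default `settle_s = 0`):
   sessions conventionally start ~30 s after the sensors are strapped on,
   so the infant settles before acquisition; the trim exists for data where
   that delay was not applied upstream.
3. **Gravity removal** (`highpass()`). Gravity appears as a ~9.81 m/s²
   offset slowly re-orienting with posture; movement energy lives well
   above ~0.1 Hz. A 4th-order Butterworth high-pass at `cutoff_hz = 0.05`
   Hz with zero phase separates the two. Numerically, the filter is applied
   in the frequency domain: each axis is odd-reflection padded by three
   filter time constants (60 s) to suppress edge transients, and its
   spectrum is multiplied by the Butterworth squared-magnitude response —
   exactly the amplitude response a forward–backward time-domain pass
   realizes, but exactly linear, exactly phase-free (jerk timing matters
   downstream), and with an exact zero at DC. The equivalent time-domain
   recursion at a normalized cutoff of $0.05/75 \approx 7\times10^{-4}$
   amplifies floating-point roundoff to ~$10^{-7}$ relative, which would
   contaminate the scale- and rotation-invariance of the final score; the
   spectral form keeps those invariances at ~$10^{-12}$. A constant axis is
   mapped to an exactly-zero axis so that movement-free channels are
   detected as degenerate downstream rather than surviving as roundoff
   residue. `zero_phase = FALSE` gives the causal single-pass response.
4. **Features** (`extract_features()`), with `max_lag_s = 2` the only
   tunable.
5. **Index** (`fit_normalization()` + `compute_kc()`), as above. Subjects
   whose features cannot be computed (e.g. a dead, zero-variance channel)
   are excluded and reported; the normalization is fitted on survivors.

Open choices settled here (the composite's definition does not fix them):
kurtosis is the Pearson, biased-moment form (Gaussian baseline 3, the
default of the numerical environments this kind of analysis is usually run
in; recorded in the config as `kurtosis_convention` for provenance); the
jerk entering the cross-correlation is the magnitude (orientation-free, so
left/right strap orientation cannot fake or destroy synchrony) rather than
a per-axis or PC1 jerk; the derivative is an unsmoothed first difference
(drift is already gone, and noise that is independent across limbs only
dilutes, never inflates, the correlation); kurtosis is computed on the
whole record rather than sub-windows; and PC1 signs are fixed by making the
first nonzero loading positive (kurtosis is sign-invariant; determinism is
the only concern).

## Cutoff machinery

Positive class = abnormal (PR ∪ CS); a subject is predicted abnormal when
its score strictly exceeds the threshold. Candidate thresholds are the
midpoints between consecutive distinct scores (±∞ sentinels); the AUC is
the trapezoidal area, identical to the Mann–Whitney concordance probability
with ties counted ½ (asserted against a brute-force pairwise oracle in the
tests). The operating cutoff maximizes Youden's $J = \text{sens} +
\text{spec} - 1$, ties broken toward higher specificity and then the lower
threshold, making the choice deterministic. Confidence intervals for both
the cutoff and the AUC come from one percentile-bootstrap engine: resamples
with replacement of the (score, label) pairs at the original size,
unstratified by default (stratified available by flag); resamples that lose
a class entirely are redrawn and counted rather than silently skipped, so
`n_boot` (default 1000) effective resamples always enter the percentiles.
The AUC interval uses the same engine rather than a closed-form method so
that one resampling mechanism, with no distributional assumptions, covers
both statistics; the DeLong interval serves as a cross-check in the test
suite only.

## The synthetic cohort generator

No public recordings of this kind exist, so `simulate_subject()` generates
the statistical structure the method assumes, as a burst point process:
each limb's acceleration is a superposition of Hann-windowed sinusoidal
bursts with per-burst amplitude, duration and frequency drawn from gamma
distributions; a fraction `coupling` of bursts comes from a stream shared
by all four limbs (same draws, per-limb timing jitter and spatial
direction — whole-body synchrony), the rest from independent per-limb
streams. A slowly re-orienting gravity vector (Ornstein–Uhlenbeck
perturbation of a random orientation, 60 s timescale, relative magnitude
0.02) and white sensor noise (0.02 m/s² RMS per axis, a few milli-g,
typical of MEMS accelerometers at this bandwidth) are added, and each
device gets its own clock offset (uniform in [0, 0.5] ms) and slightly
perturbed actual rate, reflected in its timestamps — so the synchronizer
has real work to do.

The class regimes encode the clinical descriptions: N moves often and
variedly (burst rate 0.25 Hz, amplitude CV 0.6, duration 1.2 s with CV
0.6, coupling 0.1); PR moves sparsely and stereotypedly (rate 0.08 Hz,
CVs 0.15, duration 0.6 s, coupling 0.1); CS is PR plus near-total
synchrony (coupling 0.9, shared-burst jitter 0.05 s). Burst peak
amplitude is 4 m/s² and intra-burst frequency 2.5 Hz for all groups —
plausible magnitudes for infant limb movement; the groups are deliberately
separated only by *pattern*, not by energy. These defaults are frozen: the
default cohort (43 N / 17 PR / 8 CS, the composition of a typical at-risk
follow-up cohort with roughly one-third abnormal movers) yields the group
ordering mean KC(N) < KC(PR) < KC(CS), near-perfect N-vs-abnormal
discrimination, and all CS subjects above the Youden cutoff.

Two construction properties are worth stating precisely, because one is
subtler than it looks:

* Expected jerk cross-correlation increases strictly with `coupling`
  (verified over the grid {0, 0.25, 0.5, 0.75, 1}).
* Expected PC1 kurtosis increases as movement becomes sparser *and* more
  stereotyped — the joint N-regime → PR-regime direction, and the
  burst-rate direction at any fixed amplitude CV. The amplitude CV alone,
  however, works in the *opposite* direction: for any burst-superposition
  process the amplitude distribution enters kurtosis through
  $E[A^4]/E[A^2]^2 \ge 1$, which is minimized by constant amplitudes, so
  at a fixed burst rate *reducing* amplitude variability *reduces*
  kurtosis. Sparsity (duty cycle) is the dominant driver — roughly,
  kurtosis scales like the within-burst kurtosis divided by the active
  fraction of the record — which is why the sparse stereotyped regimes
  still sit far above the normal regime. The tests assert exactly the
  properties that hold: strict monotonicity in burst rate within every
  amplitude-CV column of a 3×3 grid, and the joint-corner ordering.

What the generator does *not* emulate: biomechanical linkage between
joints, trunk movement, non-stationary behavioral states (sleep/cry
episodes), sensor saturation, or structured (non-white) sensor error.
Passing the end-to-end tests therefore demonstrates that the pipeline
measures what it claims on signals with the assumed burst/synchrony
structure — not that the clinical effect sizes, group means, or the
published cutoff value are reproduced; those were estimated on a real
cohort whose recordings are not publicly available, and the synthetic
regimes separate more cleanly than real infants do.

## Reproducibility and problem sizes

Everything stochastic is seed-controlled: cohorts draw one sub-seed per
subject up front (so subject *k*'s data do not depend on how many samples
earlier subjects consumed), and the bootstrap preserves and restores the
caller's RNG state. Re-running any CLI subcommand with the same inputs,
config and seed reproduces outputs byte-identically, which the test suite
asserts.

The packaged tests exercise the full pipeline at reduced problem sizes
chosen to keep the suite fast while leaving every effect measurable:
closed-form filter checks run at the full 600 s × 150 Hz; end-to-end
invariance uses a 6-subject cohort at ~60 s; the simulator grids use 120 s
per subject with 10 seeds per cell; the default-cohort structure check
runs all 68 subjects at 150 s. `scripts/acceptance.R` runs the complete
analysis at the full 600 s × 150 Hz with 1000 bootstrap resamples.

## Known limitations

* The cohort-range normalization makes every score cohort-relative;
  cross-study comparison requires transporting a frozen normalization, and
  a cutoff is meaningless without one (and without its normalization
  mode).
* Kurtosis on the whole record conflates within-record regime changes
  (e.g. a sleep episode) with movement character.
* The jerk magnitude discards directional information; mirrored but
  otherwise independent movements are treated identically to genuinely
  synchronous ones at the level of a single pair.
* Sample kurtosis of heavy-tailed series converges slowly; very short
  recordings (`min_duration_s` lowered aggressively) give noisy kurtosis
  features, which is why the duration guard exists.
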