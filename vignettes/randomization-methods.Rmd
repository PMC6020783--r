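---
title: "Randomization statistics for multichannel ERPs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization statistics for multichannel ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpstats)
```

## The state-space view

An average-referenced scalp map is a zero-mean vector over the n electrodes:
a point in an n-dimensional state space centered at the reference-free
origin. Two consequences drive everything in this package:

* the distance of a map from the origin, corrected for the number of
  channels, is its **global field power** (GFP), the population standard
  deviation of the potentials across channels — a reference-free measure of
  field strength;
* the distance between two maps is the GFP of their difference map, i.e. the
  overall strength of the sources that differ between the two brain states.

Because volume conduction spreads every cortical source over most of the
scalp, these whole-map quantities are the natural primitives; channel-wise
statistics answer a different (and much more multiplicity-burdened)
question.

## Tests and their null distributions

All tests share one logic: choose a GFP-based effect quantifier, destroy by
randomization exactly the structure under test, and compare. P-values use
the add-one convention p = (1 + b)/(m + 1), where b counts randomization
runs whose statistic reaches the observed one (ties count against the
hypothesis): p is then strictly positive, and when the observed data are
exchangeable with the runs the test is exact — P(p ≤ k/(m+1)) = k/(m+1).
The literal proportion b/m is available (`legacyP`) for comparability.

**Topographic consistency (TCT).** Statistic: GFP of the grand-mean map
across subjects at one time point. Null: each subject's potentials shuffled
across channels, freshly per subject, time point and run — each subject's
GFP is preserved by construction, but spatial agreement between subjects is
destroyed. A fresh permutation per time point is used because the test is
defined time-point-wise; no shared-across-time mode is offered.

**TANOVA.** Statistic: dGFP, the root-mean-square deviation (across
channels) of the factor-level mean maps from their grand mean, summed over
levels. Null: condition labels permuted uniformly and independently within
every subject; for between-subject effects, group labels permuted across
subjects. One permutation per run is shared by all effects and both the
TANOVA and the GFP test, which makes effects comparable run by run and lets
the overall statistics recycle the same null sample.

**Interactions** are tested on doubly-centered cell means (both marginal
main-effect patterns subtracted) so that a large main effect cannot
masquerade as an interaction; the raw variant is available
(`interaction = "raw"`) since the partitioning convention is a genuine
design choice. For balanced grids the residuals sum to zero across each
factor's levels.

**Normalization.** When requested, each subject × condition map is divided
by its own GFP at each time point *before* averaging — normalizing the mean
maps instead would leave subject-level strength differences inside the
level means. A sub-threshold-GFP map (eps = 1e-12 µV) is zeroed and counted
in a warning rather than producing NaNs, so permutation loops stay total.
The GFP test applies the identical machinery to the scalar GFP series of
each subject × condition map ("channels" collapsed to one value): together
the normalized TANOVA and the GFP test separate qualitative (source
configuration) from quantitative (source strength) effects.

**Rank/interval factors.** A single within factor declared rank- or
interval-scaled is tested with a linear contrast: level means weighted by
the centered level values, the dGFP formula applied to the contrast map.

## Multiple testing over time

Time-point-wise p-series invite false positives with an unknown effective
number of tests (neighbouring points are correlated). Three global
statistics summarize a p-series: the count of sub-threshold points, the
longest sub-threshold duration (× dt, in ms), and Fisher's combined
−2 Σ ln p. Each is computed on the observed series and on every
randomization run's own p-series, obtained by ranking that run's statistics
against the other runs *plus the observed data*. Pooling the observed
statistic into each run's comparison set keeps observed and null series on
the identical (1 + b)/(m + 1) grid — with a leave-one-out denominator of m
the observed series sits on a slightly finer grid, and at a threshold lying
exactly on the grid (0.05 with 100 runs) the observed count stochastically
dominates its null, inflating the family-wise error by several percent.
With the pooled construction the three overall tests are exchangeable-exact
up to ties; ties (frequent for the integer-valued count and duration at
short epochs) make them conservative, never liberal.

For the duration statistic the (1 − level) quantile of the null durations is
reported: the shortest significant period. The sub-threshold criterion
(`theta`) and the overall level (`level`) are separate arguments defaulting
to the same value; the reported threshold is non-increasing in `level` at
fixed `theta` (raising `theta` lengthens the null periods themselves, so no
monotonicity holds jointly).

## Microstates

Clustering operates on the group × condition grand-mean map series, not on
single subjects. Modified k-means assigns maps to templates by spatial
correlation and re-estimates templates from their members (polarity-aligned
mean for the ERP default `polarity = "sensitive"`; first principal axis for
`"ignore"`), keeps the best of 20 restarts, and stops when the
explained-variance gain falls below 1e-7. AAHC starts from singleton
clusters and repeatedly atomizes the cluster contributing least explained
variance — Σ (GFP·corr)² over its members, the standard criterion —
reassigning the members to their best surviving clusters; it is
deterministic. Polarity-sensitive assignment is the default because in
ERPs a sign flip is a different component; `polarity = "ignore"` serves
spontaneous-EEG-style questions.

Explained variance is Σ_t (GFP_t · corr(map_t, template_{l(t)}))² /
Σ_t GFP_t². The number of classes is chosen by split-half cross-validation
(default 50% of subjects per side, 10 splits): learning-set EV grows with
every class by construction (enforced per split via the running maximum, a
guard against k-means local optima); the test-set EV plateaus at the number
of classes that still generalizes.

Quantifier conventions (onset = first assigned sample, offset = last,
duration = count × dt, AUC = Σ GFP × dt, center of gravity = GFP-weighted
mean time, mean GFP over assigned samples) treat all of a class's samples
within the analysis window as one pool, also when the class appears in
disjoint segments — restrict the window to separate functionally different
states with similar maps. Label smoothing dissolves segments shorter than a
minimum duration (default 3 samples), shortest first, reassigning each
point to the temporally adjacent segment whose template fits better at that
point. The quantifier randomization test shuffles condition labels within
subjects (and group labels across subjects), recomputes the level grand
means, relabels them with the *fixed* templates and identical smoothing,
and compares the between-level variance of each class × quantifier against
its permutation distribution. In permutation runs a class can vanish from a
level: duration, AUC and mean GFP then enter as 0 (the class is absent),
while the timing quantifiers (onset, offset, center of gravity) of absent
classes are excluded with the variance renormalized over the present
levels — zero is a statement about occurrence, but not a latency.

## The synthetic generator

Datasets are built from k mutually orthogonal, zero-mean, unit-GFP source
maps activated in sequence with cosine-ramped envelopes (defaults: 16
subjects, 74 channels, 250 samples at 4 ms, four conditions in a 2 × 2
within design, 5 µV peak sources, 1 µV white channel noise — 20% of
signal). Condition effects are a pure strength scaling of the whole
measured field (removed exactly by normalization), a rotation of one
template within the plane it spans with an extra orthogonal map (a pure
topography change at constant GFP), and a latency shift. Subject
variability comprises amplitude gain and response latency, drawn per
subject *and condition*: each condition average is a finite-trial
measurement whose gain and latency wobble independently even without any
condition effect. This matters for validation — with variability shared
within subject, permutation differences are temporally white and the null
duration statistic degenerates to ties at 0–4 ms; with per-condition
variability the null p-series acquire the smooth, signal-shaped excursions
real averaged ERPs show, and all three overall statistics calibrate.

What the generator does not emulate: biophysical forward modeling (no
dipoles or conductor geometry — maps are abstract orthogonal patterns),
correlated sensor noise beyond an optional low-rank term, artifacts, and
non-stationary single-trial structure. Passing tests therefore demonstrate
the statistical machinery (calibration, exactness, recovery), not
robustness to real recording pathologies.

Three frozen scenarios (`syntheticScenario()`) define the validation
conditions at 12 subjects × 30 channels: `null` (no condition effect),
`amplitude` (×1.5 whole-field scaling), and `duration` (six classes over
600 ms; the third stays on 80 ms longer in one condition). Because every
sample in the analysis window belongs to some class, class durations sum to
the window length: an 80 ms gain in one class *must* be repaid by the
others, so "only one class changes" is unattainable exactly. The scenario
repays 16 ms per remaining class and sets the per-boundary timing
variability to 30 ms — realistic for late ERP components — so the
repayments drown in the permutation-null spread (measured rejection of the
other classes ≈ 10% at 0.05, ≈ 2% at 0.01 over replicates) while the 80 ms
target stays detectable at p ≤ 0.01 with 999 runs.

## Numerical and validation choices

* Randomization settings default to 5000 runs (publication standard; 1000
  suffices for the 5% level) and a 0.05 threshold; every statistical output
  records runs, seed, threshold and normalize flag.
* Windows are inclusive [from, to] in ms, endpoints mapped to the nearest
  sample; time 0 is stimulus onset unless `t0Ms` says otherwise.
* Exactness is validated against exhaustive enumeration at tiny sizes
  (all 2⁴ within-subject swaps for the TANOVA; all (3!)² channel
  permutation pairs for the TCT), with Monte-Carlo agreement required
  within 3 standard errors at 50 000 runs; calibration uses 150 null
  datasets (9000 time points) for the per-time-point tests and 200 × 100
  runs for the overall statistics — sizes chosen so the checks resolve a
  1.5 percentage-point deviation while the whole suite stays in minutes.
* The MDS outlier screen embeds the chord distance √(2(1−r)) of the
  between-subject correlations by classical scaling and applies the
  sequential one-outlier test (max Mahalanobis distance, F-form with
  Bonferroni correction) at α = 0.05; the flags are advisory and never
  auto-applied, and the union-bound correction makes the screen slightly
  conservative.
* Filters are 2nd-order Butterworth applied forward–backward (zero phase);
  order and notch width are arguments. Filtering is undoable when
  requested, restoring the stored original bit-exactly.
* Zero-variance channels in t-maps yield signed infinite sentinels (0 for
  a zero mean) with a warning, keeping the output rectangular; degenerate
  zero maps assign to class 1 with a warning.

## Known limitations

Unbalanced within-subject grids and missing cells are not supported
(complete-case import contract). Covariates and continuous between-subject
predictors are out of scope, as are single-trial analyses, source
reconstruction and resting-state microstate syntax. The count and duration
overall statistics are conservative for short epochs or few runs because of
ties on their integer grids; Fisher's statistic is the least tie-prone and
a sensible default when epochs are short.
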