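# erpstats

Randomization statistics for multichannel event-related potentials (ERPs).

## The problem

A multichannel ERP study yields, per subject and condition, a time × channel
matrix of averaged scalp potentials. Testing hypotheses channel by channel
and time point by time point multiplies tests without limit, while reducing
the data with an a-priori model (a channel subset, a component window) makes
the conclusions depend on that model. `erpstats` takes the multivariate view:
each scalp map is one point in an n-channel state space, the strength of a
map (or of a difference between maps) is its **global field power**

    GFP = sqrt( sum_j (v_j - v̄)^2 / n )

— the standard deviation of the potentials across channels — and every test
statistic built on it gets its null distribution by randomization
(shuffling condition labels within subjects, group labels across subjects,
or potentials across channels), so no parametric assumptions are needed and
all sensors enter every test.

The package implements, for users analysing averaged ERP grids
(subjects × conditions, up to two within-subject factors and one
between-subject factor):

* **TCT** — topographic consistency test: is there a common map across
  subjects at each time point? Statistic: GFP of the grand-mean map; null:
  each subject's potentials shuffled across channels (GFP-preserving).
* **TANOVA** — topographic ANOVA: do factor levels differ in map shape?
  Statistic: `dGFP = sqrt( sum_i sum_j (v̄_ij - v̿_j)^2 / n )`, the
  root-mean-square deviation of the level mean maps from their grand mean;
  null: levels shuffled within subjects. With per-map GFP normalization the
  test isolates *qualitative* (topographic) effects; the parallel **GFP
  test** handles the *quantitative* (strength) ones.
* **Overall statistics** — corrections for multiple testing over time
  (count of sub-threshold p-values, longest sub-threshold duration, Fisher's
  combined p), recycling the TANOVA's own randomization runs as the null.
* **t-maps** — post-hoc channel-wise t statistics on window-averaged
  contrasts, with a TANOVA p for the same contrast.
* **Outlier screening** — classical MDS of the between-subject correlation
  matrix with a sequential Wilks/Mahalanobis auto-select (advisory only).
* **Microstate analysis** — modified k-means and AAHC clustering of
  grand-mean maps, cross-validated choice of the number of classes, label
  smoothing, and randomization tests on per-class quantifiers (onset,
  offset, duration, AUC, center of gravity, mean GFP).
* **Synthetic data** — a generator with known ground truth (source
  templates, per-condition amplitude/rotation/latency effects, subject
  variability, noise) that backs the entire validation suite.

## Worked example

```r
library(erpstats)

# a synthetic 2-condition study: 12 subjects, 30 channels, 60 samples (4 ms)
ds  <- generateDataset(syntheticScenario("amplitude", seed = 1))
des <- erpDesign(list(cond = c(A = 1, B = 2)), conditionTags = c("A", "B"))

# strength effect present ...
gfpTest(ds, des, randConfig(nRuns = 999, seed = 2))
#> GFP test result: 60 time points, effects: cond (999 runs)
#>   fraction of time significant at 0.05: cond=0.53

# ... but no topographic effect once maps are normalized
tanova(ds, des, randConfig(nRuns = 999, seed = 2, normalize = TRUE))
#> TANOVA result: 60 time points, effects: cond (999 runs)
#>   fraction of time significant at 0.05: cond=0.08

# one p-value for the whole epoch, averaged maps
windowAverageTest(ds, des, c(0, 236),
                  randConfig(nRuns = 999, seed = 2),
                  statistic = "gfp")@p[1, 1]
#> [1] 0.002
```

The GFP test flags over half of the individual time points (the two
conditions differ ×1.5 in overall field strength; power dips where the
source envelopes ramp down), and the whole-epoch window test puts the
strength effect at p = 0.002 with 999 runs. The
normalized TANOVA stays near the nominal 5% rate: the source configuration
is identical, only its strength changed.

A command-line interface wrapping the same functions ships in
`inst/scripts/erpstats` (subcommands `simulate`, `import`, `screen`, `tct`,
`tanova`, `gfptest`, `overall`, `tmap`, `microstate`, `report`); every output
TSV records `n_runs`, `seed`, `p_threshold` and the normalize flag in its
header, so identical invocations give bit-identical files.

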