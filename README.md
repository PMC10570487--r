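# dyadsync

Interbrain phase-locking analysis for shared-gaze hyperscanning dyads.

When two people work on a joint-attention task while seeing each other's
gaze cursor, their EEG rhythms can phase-lock across brains ("interbrain
synchrony"), and their gaze trajectories coordinate. Measuring this
honestly is statistically delicate: zero-lag phase-locking measures are
inflated by any signal the two recordings share trivially (common
stimulus timing, amplifier artifacts), and "significance" must be judged
against what *unrelated* participant pairs would show. `dyadsync`
implements the full analysis chain — synthetic data generation with known
ground truth, deterministic EEG conditioning, cross-brain connectivity,
a shuffled-dyad bootstrap null model, dyadic eye-tracking metrics, and
group statistics — as composable, testable R functions.

## Core statistics

For trials n = 1…N with cross-brain phase difference
Δφₙ = φₙᴬ − φₙᴮ at one channel pair and time sample, and
m = (1/N) Σₙ exp(i Δφₙ):

- **PLV** (phase locking value): `PLV = |m|`. Sensitive to any
  consistent phase relation, including zero-lag.
- **ciPLV** (corrected imaginary PLV):
  `ciPLV = |Im m| / sqrt(1 − (Re m)²)`. Discards the zero-lag (real)
  component, so purely instantaneous coupling scores ~0.
- **wPLI** (weighted phase lag index): with cross-spectrum
  Sₙ = exp(i Δφₙ), `wPLI = |Σₙ Im Sₙ| / Σₙ |Im Sₙ|` (0/0 → 0).

Under independent uniform phases, E[PLV] ≈ √(π/(4N)) rather than 0 —
PLV is positively biased at finite N, which is why inference runs
against an empirical null: all `C(2D, 2) − D` pseudo-pairs of
participants from *different* dyads are enumerated (29 dyads → 1624
pseudo-dyads), bootstrap means of m pseudo-pair draws form the null
distribution, and each channel pair gets a z score and an add-one
two-sided percentile p value, corrected across the 32 × 32 channel grid
by Benjamini–Hochberg FDR.

Behavioral measures: target-search times from gaze-lock events
(telescoping inter-target intervals, summarized by a 10% trimmed mean),
mean inter-gaze distance in pixels, and spatial gaze heatmaps compared
per trial by Pearson correlation, SSIM, and binarized Jaccard overlap.

Group contrasts use classical repeated-measures ANOVA (with
Holm-corrected paired post hocs) and a split-plot mixed ANOVA
(within = task mode, between = dyad gender composition), both delegated
to `stats::aov()` error strata.

## Worked example

```r
library(dyadsync)

cfg <- run_config(
  sim     = sim_config(n_dyads = 3L, n_trials_per_mode = 6L, seed = 7L),
  bands   = "theta", measure = "plv",
  n_boot  = 500L, m = 100L, seed = 8L)
res <- run_pipeline(cfg)
res
#> <ibs_pipeline> 3 dyads, modes: competition/cooperation/single; bands: theta; measure: plv
#>   null [theta.competition]: 1020/1024 pairs rejected (FDR q = 0.05)
#>   null [theta.cooperation]: 1013/1024 pairs rejected (FDR q = 0.05)
#>   null [theta.single]: 857/1024 pairs rejected (FDR q = 0.05)
#>   gaze [competition]: dist = 227.4 px, jaccard = 0.505
#>   gaze [cooperation]: dist = 47.0 px, jaccard = 0.602
#>   gaze [single]: dist = 395.4 px, jaccard = 0.242
#> config hash: 8df2a257e2d14c8740ba45f5fc9a3ed9
```

The generator couples the dyads' theta oscillators (strongest in
cooperation, weaker in competition, absent in single), so rejection
counts and gaze coordination order accordingly. Set `out_dir` in
`run_config()` to write CSV artifacts plus a `manifest.json` with the
seed and config hash. A command-line front end over the same functions
is installed at `system.file("cli", "run_pipeline.R", package =
"dyadsync")` and reads real recordings via `--xdf`.

Lower-level entry points: `simulate_dyad()`, `preprocess_recording()`,
`analytic_band()`, `pair_connectivity()`, `event_connectivity()`,
`enumerate_shuffled_pairs()` / `shuffled_connectivity()` /
`ibs_null_test()`, `tst_table()`, `gaze_heatmap()` /
`heatmap_similarity()`, `rm_anova()` / `mixed_anova()`.

## Tests

```r
testthat::test_dir("tests/testthat", package = "dyadsync",
                   load_package = "installed")
```

The suite includes brute-force oracles for every statistic (direct PLV /
ciPLV / wPLI sums, manual ANOVA sums of squares, an independent FFT
Hilbert transform, hand-computed BH and bootstrap quantities).
`tests/testthat/test-acceptance.R` holds the validation contract; two of
its blocks report honest failures — the bootstrap null test is
anti-conservative by construction (its z statistic has variance ≈ m/D
under the global null; derivation in the methods vignette), and a
benchmark against an external archived behavioral deposit cannot run
offline.

## Methods

See the vignette source `vignettes/methods.Rmd` for the generative
model, filter design, the bootstrap-null variance derivation, and the
finite-N behavior of ciPLV under zero-lag coupling.
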