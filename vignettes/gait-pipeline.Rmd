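---
title: "Speed-matched gait analysis from in-shoe vertical ground reaction forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-matched gait analysis from in-shoe vertical ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgait)
```

## The problem

Gait in Parkinson's disease (PD) is typically slower, more variable and
more asymmetric than in healthy ageing. Because almost every temporal and
kinetic gait variable also changes with walking speed, a PD-vs-control
comparison at self-selected speed confounds disease effects with speed
effects. The analysis implemented here addresses that by (i) selecting a
*speed-matched* cohort — only subjects whose self-selected walking speed
falls in a fixed band (1.0–1.3 m/s, inclusive) enter the comparison — and
(ii) comparing not only scalar summaries but the entire stance-normalized
vertical ground reaction force (vGRF) curve with a one-dimensional
statistical-parametric-mapping (SPM) t-test.

The raw material is in-shoe pressure-sensor recordings: per subject, 8
sensor channels under each shoe sampled at 100 Hz, stored as plain
19-column text (time, 8 left channels, 8 right channels, left total,
right total). `pdgait` turns these into per-stride temporal and kinetic
features, per-subject summaries (means, coefficients of variation,
symmetry indices), and group-level tables plus the SPM comparison.

## Processing chain

1. **Sensor summation.** The per-foot vGRF `Fz` is the row-wise sum of the
   8 channels of that shoe; the total `Fz,tot` is the sum over both feet.
   Stored per-foot totals in the input files are only cross-checked (to
   0.5 N); the pipeline always recomputes them.
2. **Denoising.** Force values strictly below 20 N are replaced by zero.
   The floor is applied to the per-foot summed signals, not per channel.
3. **Filtering.** A 4th-order low-pass Butterworth at 15 Hz, applied
   forward and backward (zero phase). Denoising precedes filtering; the
   pipeline enforces and records this order.
4. **Startup trim.** The first 5 s of each recording are discarded; times
   are not re-zeroed.
5. **Event detection.** Foot-strike (FS) is the first sample at or above
   20 N after a sub-threshold run, toe-off (TO) the first sample strictly
   below it; phases shorter than 100 ms are merged (debounce). Events are
   reported at sample resolution — no sub-sample interpolation.
6. **Stride assembly.** For each same-foot FS→FS cycle, the frame
   `fs < contralateral_to < contralateral_fs < to < next_fs` is checked;
   violating frames are excluded and counted in the QC report.
7. **Turn exclusion.** Strides whose duration deviates from the subject's
   median by more than 3 scaled MADs are flagged as turns, together with
   one neighbouring stride on each side of each flagged run.
8. **Features, summaries, and group statistics** (below).

## The variables

Per stride (durations in ms, also as % of stride; forces in body weights,
BW = body mass × 9.80665 m/s²):

* stride time (FS to next FS), stance time (FS to TO), single support
  time (contralateral TO to contralateral FS, equal to the contralateral
  swing), double support time;
* `Fz,peak1`, `Fz,peak2`: maxima of the first and second half of stance
  (halves split at 50% of stance duration, ties to the earliest sample),
  with their times relative to FS;
* `Fz,tot,peak`: maximum of the total force during the stance window;
* weight-transfer dynamics: `Fz,peak front` (first strict local maximum of
  the striking foot's force after its FS), `Fz,peak back` (last strict
  local maximum of the other foot's force before its TO), their signed
  difference `ΔFz` and the signed time between them (`gwt`).

Per subject, every variable is averaged per foot across included strides;
the reported mean is the average of the left and right means. Variability
is the coefficient of variation, CV = 100·sd/mean with the sample (n−1)
standard deviation, computed per foot and averaged. Asymmetry is the
symmetry index computed from the two per-foot means,

SI = |x_R − x_L| / (0.5·(x_R + x_L)) · 100,

zero for a perfectly symmetric gait.

Group comparisons use the classic pooled-variance unpaired two-sided
Student's t-test, and a Pearson correlation relates disease severity to
walking speed within the PD group. For the curve-level comparison each
subject contributes one mean stance-normalized curve (101 points, 0–100%
of stance, linear interpolation); the two-sample t statistic is computed
at every grid point, and the family-wise critical threshold is the 95th
percentile of the permutation distribution of max|t| over group-label
permutations (complete enumeration when feasible, otherwise seeded
Monte-Carlo permutations).

## Design choices where the design was open

* **Per-stride double support.** One stride sees two double-support
  occurrences (leading and trailing). Reporting their *mean* makes one
  stride contribute one number on the per-occurrence scale (≈14% of the
  stride), which is the scale on which double support is conventionally
  tabulated; the sum (≈27%) is available via
  `pipeline_config(double_support = "sum")`.
* **SI uses the absolute difference.** Signed indices would cancel in
  group averaging; the absolute form makes 0 mean "symmetric" and keeps
  group means positive.
* **CV uses the n−1 sample SD.** The package documents the convention and
  applies it uniformly.
* **Zero-phase filtering.** Forward–backward application squares the
  magnitude response and removes phase delay, so detected events are not
  shifted by the filter's group delay. The filter is designed with
  `signal::butter`; the two passes are run over an odd-reflection-padded
  copy of the signal so that edges carry no start-up transient (a constant
  signal is reproduced to machine precision).
* **Permutation SPM instead of random-field theory.** The permutation
  max-statistic threshold is assumption-light, exactly testable by
  enumeration on small groups, and controls the family-wise error at the
  nominal level (verified by a 200-repetition null calibration in the test
  suite). Random-field-theory thresholds are deliberately out of scope.
* **Event timing at sample resolution.** At 100 Hz the grid is 10 ms;
  millisecond-scale reporting does not warrant sub-sample interpolation,
  and on-grid events make detector behaviour exactly testable.
* **Automated turn removal.** The corridor protocol's turns were removed
  manually in the original studies; the median ± 3·MAD rule with
  run-neighbour expansion is a conservative, parameter-light automated
  proxy. It approximates, not replicates, a manual step. When most stride
  times are literally identical (noise-free synthetic gait) the MAD is
  zero and any departure from the median is treated as an outlier.
* **Threshold semantics.** FS uses ≥ 20 N, TO uses < 20 N, mirroring the
  strict-< semantics of the 20 N denoising floor.
* **g = 9.80665 m/s²** for the BW conversion.
* **One curve per subject enters the SPM test** (the mean over that
  subject's included strides), avoiding pseudo-replication.
* **No multiple-testing correction across the scalar tables** — each table
  reports per-variable p values as is; this is stated rather than hidden.

## The synthetic gait generator

All testing runs on synthetic cohorts with known ground truth
(`simulate_subject()`, `simulate_cohort()`), which emulate the statistical
structure the analysis relies on:

* **Stance profile.** The per-foot vGRF over one stance is
  `A·(sin(πu) + r·sin(3πu))` in BW on normalized stance position
  `u ∈ [0,1]` — the minimal closed form with the canonical two-peak shape.
  With the defaults `A = 1.25`, `r = 0.40` the peaks are ≈1.24 BW and
  their exact location is recoverable by root-finding on the derivative,
  which gives the test suite an analytic oracle for every peak feature.
* **Timing.** Step durations are i.i.d. Normal draws (each foot's stride
  time, the sum of two consecutive steps, then has the requested mean and
  CV); the left-to-right step is lengthened by the asymmetry offset and
  the right-to-left step shortened by it. Each stance ends one
  double-support duration — (stance fraction − 0.5) of the stride — after
  the contralateral foot-strike. Double support is therefore emergent from
  overlapping stances, phase accounting (single support left + right +
  both double-support components = stride) holds *exactly* on the ground
  truth, and the asymmetry offset propagates into single-support and
  stance times, as in asymmetric gait, while leaving double support
  symmetric.
* **Defaults as study conditions.** Stride time 1071 ms with 2.2%
  within-subject CV (PD-like) vs 1107 ms with 2.1% (control-like); stance
  fraction 0.637, so each double support spans 13.7% of the stride;
  between-subject stride-time SD 80 ms; body mass 73 ± 11 kg; walking
  speeds uniform in 1.05–1.25 m/s so the 1.0–1.3 m/s selection band is
  exercised; a 90 s walk yields ≈73 strides per foot after trimming,
  matching the per-subject stride counts of corridor protocols. Cohorts
  add between-subject amplitude SD 0.10 BW and a per-subject asymmetry
  offset with SD 10 ms, which reproduces single-support symmetry indices
  of a few percent, and draw the PD severity score correlated (r ≈ 0.36)
  with walking speed — the counterintuitive positive association a narrow
  speed band induces.
* **Nuisance structure.** 8-channel sensor decomposition by fixed
  nonnegative weights summing to 1; optional i.i.d. Gaussian sensor noise
  truncated at 0 N; a 2 s startup ramp (removed by the 5 s trim); optional
  turn segments of 3 strides with stride times inflated 1.5× at a
  configurable period, giving the turn-exclusion rule something detectable.
* **What it does not model.** Within-subject force-peak variability is off
  by default (`amplitude_jitter_cv = 0`): no variability model is asserted
  where none is established, so force CVs on default synthetic cohorts are
  near zero and only timing variables carry realistic CVs.
  Mediolateral/anteroposterior forces, freezing-of-gait episodes,
  musculoskeletal detail and spatial variables (stride length, speed from
  forces) are out of scope. Because the stance profile is left-right
  symmetric in shape, the total-force peak is a near-tie between the two
  double-support windows of a stride; its *timing* is therefore bimodal on
  synthetic data (and its CV/SI inflated), a known property of the
  generator rather than of the pipeline.

Passing tests on this generator demonstrate that the pipeline recovers
known timing, force, variability and asymmetry structure through the full
signal chain; they cannot certify behaviour on pathologies the generator
does not emulate (sensor dropout, drift, freezing episodes, genuinely
asymmetric force shapes).

## Numerical choices and degenerate inputs

* Events on the 10 ms grid: on noise-free synthetic data the raw detector
  (floor → threshold) reproduces the ideal continuous-time 20 N crossing
  rounded up to the grid *index for index*; the 15 Hz zero-phase filter
  can move a crossing by at most one sample (it slightly smears the
  contact edge), so full-pipeline event times are asserted to within one
  sample of ground truth.
* Filter padding: reflection padding of up to 300 samples absorbs the
  zero-state transient; signals shorter than 3·(order+1) samples are
  rejected with an instruction to skip filtering.
* Ties in peak picking go to the earliest sample; plateau stances are
  flagged (`single_peak_flag`) rather than dropped.
* CV is undefined (NA) for n < 2 or nonpositive mean; SI is undefined when
  the left+right sum is nonpositive (e.g. signed `ΔFz` near zero) — such
  entries propagate as NA with reduced n, never as zeros. The near-zero
  group mean of `ΔFz` makes its CV essentially unstable by construction;
  it is reported as computed.
* Zero-variance grid points in the SPM input (e.g. the first and last
  stance sample in noise-free data) are dropped from max|t| with a
  warning; if all points are degenerate the threshold is infinite and no
  clusters are reported.
* A subject with fewer than 2 included strides on either foot is excluded
  from cohort tables with a warning; a subject-level failure is isolated
  and logged by `run_extract()`, never fatal for the cohort.

## Problem sizes used by the test suite

The suite's heavier checks use sizes chosen to make sampling error small
relative to the asserted tolerances while staying desk-scale: the
null calibration of the SPM threshold runs 200 repetitions of 15-vs-15
subject curves with 2000 permutations each; the effect-size recovery runs
a full 54-vs-39 cohort at 90 s walks once, plus 50 seeded replicate
cohorts at 40 s walks for the stride-time power check (the detection power
of a 36 ms stride-time difference over an 80 ms between-subject SD at
these group sizes is ≈0.56 analytically, and subject-mean estimation error
at ≈36 strides contributes ≈4 ms, negligible against 80 ms).

## Known limitations

* The turn rule is a statistical proxy; slow deliberate turns with
  near-normal stride times would evade it.
* Speed is consumed from the demographics table, not estimated from the
  force records (no spatial information is available in vGRF alone).
* The SPM comparison inherits the stance-normalization convention;
  features that shift in absolute time but not in relative stance position
  are invisible to it.
* On synthetic cohorts whose groups differ strongly in stance duration,
  the interaction of a fixed-bandwidth filter with time normalization can
  produce small systematic curve differences near the stance edges; with
  realistic between-subject variation these stay well below the
  permutation threshold.
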