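---
title: "Methods: individualized slow-oscillation/spindle coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized slow-oscillation/spindle coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

During non-REM sleep, cortical slow oscillations (SO, < 2 Hz) and
thalamo-cortical sleep spindles (10–18 Hz) coordinate in time: spindles
preferentially occur in a particular phase of the SO cycle, and the
precision of that coordination is a candidate mechanism of sleep-dependent
memory consolidation. Two obstacles make this hard to quantify fairly
across individuals or age groups:

1. **The aperiodic background moves.** EEG power spectra are dominated by a
   `1/f^β` "fractal" component whose offset and slope change with age and
   state. Raw band power therefore confounds oscillations with background.
2. **Oscillation frequencies are individual.** Spindle peak frequency
   varies by several Hz between subjects (and rises during development), so
   fixed-band detectors measure different things in different people.

`socoupling` implements the resulting analysis chain: time-domain
z-normalization → IRASA separation of fractal and oscillatory spectra →
individualized SO/spindle peak parameterization → percentile-threshold
event detection at the individual peak frequency → event-locked
cross-frequency coupling with circular statistics → group-level cluster
permutation and correlation inference. A synthetic polysomnography
generator provides exact ground truth for every stage.

# Spectral model and IRASA

Power spectra use Hann-tapered FFTs on 15-s windows slid in 1-s steps,
restricted to windows lying entirely inside the artifact-free stage mask;
power is averaged across windows and log10-transformed (frequency grid
0.13–30 Hz at the native 1/15 Hz resolution).

IRASA resamples each segment by factors `h = 1.1, 1.15, …, 1.9` and by the
reciprocal `1/h`. Read at the nominal rate, resampling moves an
oscillatory peak at `f0` to `f0/h` (or `f0·h`) while a power law
`f^(−β)` reproduces itself up to a factor `h^(β−1)` that cancels
**exactly** in the geometric mean of each `(h, 1/h)` pair. The median
across the 17 factors then suppresses the shifted oscillatory peaks,
leaving the fractal component; the oscillatory residual is
`mixed − fractal` in log space.

Two estimator-order decisions matter numerically, and both were made for
unbiasedness:

* **Reciprocal pairing.** Pairing `h` with `2 − h` instead of `1/h` does
  not cancel a power law (the error reaches ~0.25 log10 units at `β = 2`,
  `h = 1.9`); the reciprocal pairing of the original IRASA algorithm is
  used.
* **Average windows first.** Single-window periodograms are approximately
  chi-squared with two degrees of freedom. Taking a geometric mean of two
  quasi-independent such estimates *before* averaging across windows biases
  the fractal estimate by `E[√(P₁P₂)] = (π/4)·m` (−0.105 log10), and the
  median across factors compounds this to roughly −0.25 log10. The
  implementation therefore averages periodograms across windows per factor
  and direction first, then takes the geometric mean and the median. With
  this order the residual on pure `1/f^β` input is unbiased to within
  ±0.03 log10 units (measured over 20 seeds).

Resampling is performed in the Fourier domain (spectral truncation /
zero-padding, the classical band-limited resampler); target lengths are
rounded to 5-smooth integers so that all FFT lengths stay mixed-radix
friendly, with the actual achieved ratio used in all bookkeeping, so the
rounding is exact rather than approximate.

Band peaks are local maxima of the residual (sign change of the first
difference), the largest positive one inside the band: SO < 2 Hz, spindle
10–18 Hz; ties go to the lower frequency. The theta band is exposed as a
configurable band with the conventional 4–8 Hz default (the band limits
are not canonical; treat them as a convention, not a measurement).

# Event detection

Both detectors follow the percentile-threshold family of algorithms and
are individualized per channel through the spindle peak frequency from the
oscillatory residual.

**Slow oscillations.** The trace is high-pass filtered at 0.16 Hz
(transition width 0.1 Hz) and low-pass filtered at 2 Hz (0.5 Hz), both as
zero-phase Hamming-window FIR filters (symmetric kernels applied with
exact group-delay compensation; zero phase distortion is required because
the phase of the filtered signal is the coupling observable downstream).
Candidates are intervals between consecutive positive-to-negative zero
crossings (sub-sample interpolated), keeping those lasting 0.8–2 s;
events are candidates whose trough-to-peak amplitude strictly exceeds the
75th percentile of all duration-valid candidate amplitudes. Note the
consequence: **this is by construction a top-quartile detector.** When
validating against synthetic ground truth, recall is scored against the
top amplitude quartile of injected events (its design contract), precision
against all injected events.

**Spindles.** The trace is band-pass filtered ±2 Hz around the individual
spindle peak, the Hilbert envelope is smoothed with a 200-ms centered
moving average, and events are runs strictly above the 75th percentile of
the masked envelope lasting 0.5–3 s; the anchor is the envelope maximum.
Because the threshold is a sample percentile, 25% of masked samples always
lie above it; when spindle bursts occupy clearly less than 25% of the
mask, some background envelope excursions of ≥ 0.5 s are inevitable
detections — an intrinsic property of the published algorithm, not a
tunable defect. At the generator's default occupancy (~18%) measured
spindle precision is ~0.94 with recall ≈ 0.99 (SO detector: 1.00/1.00
under its top-quartile contract). Detection thresholds are computed on the
pooled NREM2+NREM3 mask so that stages share one criterion; adjacent
supra-threshold runs are not merged; events overlapping rejected 5-s
artifact bins are excluded by mask intersection.

# Event-locked coupling

Coupling is estimated from events, not comodulograms: ±2.5-s epochs around
each NREM3 spindle peak are individually z-scored, low-pass filtered at
2 Hz, and the analytic-signal phase is read at the center sample. The
convention is 0 = SO positive peak (up-state), ±π = trough. Summaries are
the circular mean (preferred phase), the resultant length (coupling
strength / phase-locking value, reported without small-sample bias
correction; under uniformity its expectation is `√π/(2√n)`), the
percentage of events within ±22.5° of the preferred phase (boundary
inclusive), and the absolute circular distance of the preferred phase to
0° as the linearization used for repeated-measures statistics. A
bootstrap (500 events × 100 draws, seeded) controls comparisons for event
count. NREM2 coupling is not computed by default (co-occurrence there is
too low for stable estimates) but is one config switch away, as is the
fixed 11–15 Hz band control analysis (`individual_peaks = FALSE`).

The SO-trough-locked time-frequency map uses 500-ms Hann windows, −2 to
2 s in 50-ms steps, 5–30 Hz in 0.5-Hz steps, z-scored against a
bootstrapped baseline: trials are resampled 10 000 times, the −2 to −1.5 s
trial-average is collected **per baseline time bin** (pooling the bins
into the bootstrap distribution), and the resulting mean/SD standardize
the map. Pooling matters: averaging the baseline bins before taking the
SD shrinks it below the scale of single map bins (the STFT windows
overlap, so the baseline span holds ~2 independent estimates) and inflates
|z| by ~√2; with pooling, ≥ 99% of null-map bins fall inside |z| ≤ 3.

# Group-level inference

Cluster-based permutation tests use pointwise paired t (or Spearman rho
transformed to t) statistics, a two-sided `cluster_alpha = 0.05` forming
threshold, clusters by adjacency (1-D grids: neighboring bins; channels: a
shipped 10–20 neighbor table), the **maximum cluster size** statistic, and
a sign-flip (or outcome-shuffle) null of the per-permutation maximum
(1000 permutations, seeded); p-values are `(1 + #{null ≥ obs})/(B + 1)`.
Measured calibration: family-wise error 0.04–0.06 at nominal 0.05, power
> 0.95 for a 1-SD shift spanning 6 of 30 bins at n = 20.

The correlation family: Spearman via base R, partial Spearman by the
rank-residual method (when the covariate explains a variable completely
the partial correlation is reported as 0), the conventional
circular-linear multiple correlation, and the Jammalamadaka–SenGupta
circular-circular coefficient (other toolboxes may differ in the third
decimal; the statistic is the standard one). Dependent overlapping
correlations are compared with a percentile bootstrap (subjects resampled
with replacement, dependency preserved; p = 2·min tail with add-one
smoothing; Z = bootstrap mean/SD). Cohen's d for paired data is
mean/SD of the differences; cluster effect size averages pointwise d over
cluster members. Recall on the word-pair task scores semantically correct
answers at half weight: `100·(correct + 0.5·semantic)/total`.

# The synthetic generator: what it emulates, what it does not

`gen_coupled_recording()` builds: Gaussian `1/f^β` background synthesized
in the frequency domain (β = 2, SD 15 µV by default, with the N2
background offset 0.3 log10 lower than N3); biphasic SO cycles
(trough-then-peak single sine cycles, 0.9–1.4 s, 75–300 µV) placed by a
non-overlapping renewal process at 10/min in N3 and 2/min in N2; and
Hann-windowed spindle bursts (0.8–1.8 s, 10–40 µV, default 13 Hz) whose
centers are **phase-targeted**: a phase is drawn from von Mises(μ, κ) and
the burst is centered where the Hilbert phase of the 2-Hz-low-passed,
noise-free SO component attains it — the same convention the measurement
side uses, which makes the recorded ground-truth phase exact rather than
nominal. Defaults: μ = 33.5° (spindles near the up-state), κ = 4.
Uncoupled spindles are placed uniformly away from SOs (1/min N3, 2/min N2,
making N2 co-occurrence low, as in real sleep).

The generator does **not** emulate K-complexes, eye or muscle artifacts,
topographic field spread (channels are independent given the parameters),
spindle frequency drift within a burst, or non-Gaussian background
transients. Passing the validation suite therefore demonstrates that the
estimators are correct for the stated signal model — not that the
detectors are robust to every artifact class of real polysomnography.

`gen_cohort()` draws paired "childhood/adolescence" subjects: spindle peak
11.5 ± 0.5 Hz → 13.3 ± 0.5 Hz, background slope 2.2 → 1.8, SO amplitudes
slightly decreasing, and coupling concentration κ ~ lognormal(log 0.7,
0.7) → lognormal(log 2.2, 0.7). This κ range reproduces the wide
between-subject spread of coupling strength seen in developmental data
(roughly 0.2–0.7) and rises across timepoints; delayed recall at the
second timepoint follows `a + b·(κ_t2 − κ_t1) + noise` (a = 55, b = 2,
noise SD 2 by default), tying the behavioral change linearly to the
coupling-concentration change. Because the pipeline measures the
*resultant* R(κ), which saturates above κ ≈ 3, and estimates it from a
finite number of events, the recoverable subject-level correlation between
measured coupling change and recall change is bounded near 0.7–0.8 even
with noise-free behavior; the validation suite therefore evaluates cohort
recovery in a strong-effect regime (b = 5, behavior noise 0.5, fully
coupled spindles) where the built-in effect is near that ceiling.

# Problem sizes and numerical choices

Validation runs use desk-scale problem sizes chosen as the package's
standing protocol: 60-s spectra at 128 Hz (20 seeds per condition),
10-minute recordings for detector scoring (10 seeds), a 60-minute fully
coupled N3 stretch for the κ-sweep (~580 coupled events per condition,
which keeps the κ = 0 resultant noise floor `√π/(2√n)` well inside the
tolerance), 20 + 20 synthetic
cohorts of 14 subjects × 2 timepoints × 2 frontal channels with 7-minute
N3 recordings, and 200 null + 100 power simulations for the cluster test.
The subject pipeline caps the spectra used for peak estimation
(`spectral_max_sec`) at 20–60 s in these runs; peak estimates from 30 s
are within ~0.16 Hz of those from the full recording.

Other numerical conventions: population (divisor-n) SD for all
z-normalizations; normalization statistics estimated on artifact-free NREM
samples but applied to the whole trace so epochs anywhere share one scale;
strict `>` at percentile thresholds (degenerate constant-envelope input
yields zero events rather than everything); boundary-inclusive windows
(co-occurrence at exactly 2.5 s, preferred-phase radius at exactly 22.5°);
epoch low-pass with odd-reflection padding; the trough must precede the
peak within an SO candidate; unknown hypnogram tokens map to `Unknown`
with a warning and are excluded from every analysis mask; events are
dropped (not trimmed) when they touch rejected bins or recording edges.

# Known limitations

* The spindle detector's precision is occupancy-limited (see above);
  on sparse-spindle recordings a fixed-amplitude or candidate-percentile
  variant would be more precise, but would no longer be the published
  algorithm.
* The EDF writer/reader covers continuous 16-bit recordings with one
  sampling rate; EDF+ annotations are out of scope.
* Channel adjacency ships for the 11-channel 10–20 montage only; custom
  montages need a user-supplied neighbor table.
* Circular-circular correlation follows Jammalamadaka–SenGupta; small
  numeric differences from other implementations are possible.
* The cohort generator's behavioral model is linear in κ-change by
  design; through the saturating resultant this bounds recoverable
  correlations (measured and documented above), which mirrors a real
  limitation of event-based coupling estimates at modest event counts.
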