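---
title: "Detecting axon bundle activation from multi-electrode stimulation scans"
author: "bundleScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting axon bundle activation from multi-electrode stimulation scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundleScan)
```

## The problem

Epiretinal prostheses stimulate retinal ganglion cells (RGCs) through a
multi-electrode array (MEA) pressed against the retinal surface. Between
the electrodes and the target somas runs the nerve fiber layer: the axons
of distant RGCs whose somas — and therefore receptive fields — lie off
the array. When a stimulation current recruits one of these passing
axons, the evoked percept cannot be localized or controlled. For safe
calibration, one needs, for every stimulating electrode, the *bundle
threshold*: the lowest current amplitude at which off-array axonal
activation appears. `bundleScan` estimates these thresholds automatically
from the electrical recordings themselves, replacing a manual
movie-review workflow that scales poorly to arrays with hundreds of
electrodes.

The input is a single-electrode stimulation scan: each electrode is
stimulated repeatedly (n repeats, 25 by default) at each level of an
increasing amplitude grid (40 levels growing 10% per step from 0.1 µA by
default), while all electrodes record at 20 kHz. The recorded voltage
decomposes as

$$y = x + i + s + n,$$

evoked activity $x$, stimulation artifact $i$, spontaneous spiking $s$,
and recording noise $n$. Only $x$ matters for the threshold; the pipeline
is built around three physiological facts:

1. **Temporal precision.** Electrically evoked spikes recur at a
   consistent sub-millisecond latency across repeats (≈0.1 ms jitter),
   while spontaneous spikes and noise minima are random in time.
2. **Monotonicity.** Once an amplitude reliably evokes a spike, all
   higher amplitudes do too.
3. **Bidirectional propagation.** An activated axon conducts both ways
   from the stimulation site along a nearly straight path, so bundle
   activation reaches (at least) two opposite ends — two *borders* — of
   a rectangular array.

## The five detection steps

For one stimulating electrode, with $V_{a}(r, e, t)$ the voltage at
amplitude $a$, repeat $r$, recording electrode $e$, sample $t$:

1. **Artifact subtraction.** $v_a = V_a - \mathrm{mean}_r
   V_{a_{\min}}$. The lowest grid amplitude serves as the artifact
   reference; the estimate is *not* rescaled with amplitude. Any
   repeat-independent signal applied identically at all amplitudes
   cancels exactly, so detection is invariant to the artifact's shape by
   construction (`subtractArtifact()`).
2. **Spike times.** $t_a(r, e) = \arg\min_t v_a(r, e, t)$ over the
   analysis window 0.3–2 ms after the stimulus (extracellular spikes are
   negative; the early blank skips the residual artifact). At 20 kHz the
   window is samples 7..41, $m = 35$ samples (`extractSpikeTimes()`).
3. **Signal electrodes.** Under the null of no evoked activity the spike
   time is uniform over the $m$ window samples, with variance
   $\sigma_0^2 = (m^2-1)/12$ (= 102 for $m=35$). The sample variance
   across $n$ repeats then satisfies, approximately,
   $(n-1)s^2/\sigma_0^2 \sim \chi^2_{n-1}$. An electrode is flagged as
   carrying evoked activity when $s^2$ falls strictly below
   $c = \sigma_0^2 \, Q_{\chi^2_{n-1}}(p)/(n-1)$ — about 58.9 samples²
   for $n = 25$, $p = 0.05$ (`varianceCutoff()`,
   `extractSignalElectrodes()`). $p$ is the pipeline's only model
   hyperparameter. The discrete uniform is platykurtic relative to the
   chi-squared approximation, so the realized false-flag rate is ≈1%,
   conservative with respect to the nominal level.
4. **Pruning.** $\mathrm{Act}(a_j) = \bigcap_{k \ge j}
   \mathrm{Sig}(a_k)$, computed from the top amplitude down. This
   enforces monotonicity: a genuinely activated electrode stays flagged
   at all higher amplitudes, while stray flags rarely persist. The
   activated sets are nested by construction
   (`pruneSignalElectrodes()`).
5. **Border rule.** The bundle threshold is the lowest amplitude whose
   activated set touches at least two distinct borders of the array
   (first/last row, first/last column). If no amplitude qualifies the
   result is an explicit not-found state, never a clamped value
   (`detectBundleThreshold()`).

By nesting, the qualifying amplitudes are upward-closed, so the first
qualifying amplitude is well defined. `runDetection()` applies all five
steps independently per stimulating electrode.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pValue` | 0.05 | — | level of the variance test; the only model hyperparameter. Performance is flat over 0.02–0.08 because pruning immediately follows the test. |
| `windowStartMs`, `windowEndMs` | 0.3, 2 | ms | spike-time window; the lower edge blanks the artifact, the upper edge accommodates propagation delays across the array. |
| `minBorders` | 2 | — | distinct borders required; 2 is the bidirectionality signature. |
| `cornerRule` | `"literal"` | — | a lone corner electrode lies on two borders and satisfies the rule by itself; `"two-electrode"` demands distinct electrodes on distinct borders (a maximum-matching test), trading literal fidelity for robustness. |
| `excludeRecording` | none | — | optional electrode exclusions; the stimulating electrode's own recording is kept by default, the window blank being the artifact mitigation. |

Numerical conventions: electrodes and grid levels are indexed 1-based
row-major; the window is the inclusive sample range
$[\lceil t_0 f_s \rceil, \lfloor t_1 f_s \rfloor]$; argmin ties resolve
to the earliest sample; the sample variance uses denominator $n-1$,
matching the $\chi^2_{n-1}$ scaling; the comparison with the cutoff is
strict; $a_{\min}$ is excluded from candidate thresholds (its
artifact-corrected traces are zero-mean residuals by construction).

## The synthetic scan generator

Real scans of this kind are not publicly deposited, so the package
carries a simulator (`simulateScan()`, `SimulationConfig()`) that
generates the four components explicitly and records ground truth:

- **Evoked ($x$).** Each stimulating electrode owns a straight axon
  path through its position at a random orientation. Electrodes within
  `captureRadiusUm` (45 µm) of the line record the bundle spike — a
  negative Gaussian waveform (peak 60 µV, width 0.05 ms) arriving at
  `baseLatencyMs` + distance/`conductionVelocity` (0.5 ms, 1 m/s) plus
  Gaussian jitter (0.05 ms), bidirectionally from the stimulation site.
  The 45 µm radius represents the lateral spread of the recorded
  compound bundle signal; being above half the 60 µm pitch, it also
  guarantees at least one captured electrode on each border the line
  crosses. Activation per trial follows a logistic curve in
  log-amplitude (scale `activationSlope` = 0.015, i.e. a 10–90% width of
  ≈6.6% of amplitude — a steep single-axon activation curve — centred
  half a grid step below the drawn threshold level). One uniform draw
  per repeat is shared across amplitudes, so per-repeat activation is
  non-decreasing in amplitude, the premise of the pruning step. The
  ground-truth threshold is the lowest grid amplitude whose activation
  probability reaches `truthLevel` (0.5); with a step curve
  (`activationSlope = 0`) this coincides with certain activation.
- **Artifact ($i$).** A damped oscillation (1 mV peak, 0.05 ms decay,
  2 kHz), scaled linearly with amplitude and attenuated as
  $1/(1+(d/\mathrm{pitch})^2)$ with distance from the stimulating
  electrode. It decays below the noise floor before the analysis window
  opens, emulating hardware whose artifact suppression permits
  sub-millisecond response detection. Because it scales with amplitude,
  it does *not* cancel exactly in step 1 — matching reality — and the
  window blank is what protects detection.
- **Spontaneous ($s$).** Poisson spikes (10 Hz per electrode, 80 µV) at
  uniform times, independent across trials.
- **Noise ($n$).** White Gaussian noise, 10 µV sd.
- **Somatic component** (optional, off in the validation conditions): a
  local cluster within 75 µm of the stimulation site activating at 60%
  of the bundle threshold — unidirectional, near-field activity that
  must not trip the border rule. It is exercised in dedicated tests;
  placed at a corner, a somatic cluster would legitimately satisfy the
  literal border rule, which is informative as a test but not as
  background in the packaged validation scan.

All randomness flows from one master seed: scan-level draws
(orientations, thresholds, coupling uniforms, per-electrode sub-seeds)
happen once in a fixed order, and each stimulating electrode's traces are
generated from its own sub-seed. A block is therefore bit-reproducible in
isolation, which is what lets `runValidationStudy()` stream scan-scale
detection one stimulating electrode at a time (the packaged 16×16, 40
amplitude, 25 repeat validation scan would otherwise hold ~2.7×10⁹
voltage samples). Optional components are drawn after the core ones, so
disabling them leaves the noise and spontaneous draws bit-identical — a
property the somatic tests rely on. `simulateSpikeTimes()` is a fast
distributional shortcut to the post-step-2 state for statistical tests of
steps 3–5.

### What the generator does and does not emulate

It reproduces the statistical structure the detector relies on:
time-locked evoked spikes with monotone activation, bidirectional
propagation to two borders, an amplitude-dependent repeat-independent
artifact, uniform-in-time nuisance spikes, and white noise. It does not
model curved axon paths, multi-axon bundles with heterogeneous
thresholds, electrode-specific noise or impedance, correlated (e.g.
rhythmic) spontaneous activity, or artifact waveform idiosyncrasies
beyond the damped-oscillation family. Passing the packaged validation
therefore demonstrates correctness of the pipeline under the model's
assumptions, not performance on any particular preparation; the
artifact-invariance property is what extends the conclusion to arbitrary
repeat-independent artifact shapes.

### Validation conditions and experiment sizes

The packaged validation configuration (`validationConfig()`) is a 16×16
array at 60 µm pitch — 256 stimulating electrodes, enough to estimate
agreement fractions to a few percent — with the standard 40-level grid,
25 repeats, and the moderate noise/jitter/spontaneous settings above.
True thresholds are drawn uniformly from grid indices 14–36
(0.35–2.8 µA, the range where bundle thresholds typically fall).
`runValidationStudy()` runs full detection plus ten random 15-of-25
repeat subsets in a single streaming pass (a few minutes on one CPU).
Unit tests use 6×6 and 8×8 scans with shortened grids, where a full
tensor fits comfortably in memory.

## Known limitations

- **Early-by-one false positives.** At the amplitude just below a true
  threshold, every higher amplitude is genuinely flagged, so pruning
  cannot protect against a chance flag there; with the literal corner
  rule a single false-flagged corner electrode of the path suffices.
  This happens at roughly the variance test's realized false-positive
  rate (~1% per electrode, slightly above the uniform-null value because
  the subtracted artifact reference carries shared sampling noise of sd
  $\sigma/\sqrt{n}$ that weakly correlates repeats). The deviation is
  bounded at one grid step and biased early, never late.
- **Top-of-grid false positives on silent electrodes.** At the highest
  amplitude the pruning intersection is trivial, so a pure-noise scan
  can occasionally report a threshold at (or just below) the top of the
  grid when two chance flags land on distinct borders. Reported
  thresholds at the last one or two grid levels of an otherwise silent
  electrode warrant inspection.
- **Window versus array size.** Evoked spikes must arrive inside the
  2 ms window: with 1 m/s conduction and 0.5 ms base latency the farthest
  reachable distance is 1.5 mm, ample for a 16×16 array (diagonal
  1.27 mm) but not for arbitrarily large geometries — scale
  `conductionVelocity` or the window accordingly.
- **Degenerate noiseless input.** With exactly zero noise every silent
  electrode has a deterministic argmin (the tie-break sample), zero
  variance, and is flagged everywhere, so the border rule fires at the
  lowest amplitude for all electrodes. The variance test presupposes a
  noise floor; the package's clean-recovery tests therefore use a 1 µV
  floor far below the 60 µV spike rather than literal silence.

## File formats

Scans are stored in a single HDF5 container (`writeScan()`/`readScan()`):
datasets `/voltages` — the 5-D tensor (stimulating electrode × amplitude
× repeat × recording electrode × sample), chunked along the
stimulating-electrode axis so one electrode streams independently — and
`/amplitudes`, with root attributes for the sampling rate, the
stimulating electrodes, and a JSON geometry descriptor. Thresholds travel
as CSV (`stim_electrode`, `threshold_uA`, `threshold_index`, `status`)
plus a JSON run summary (`writeThresholds()`/`readThresholds()`). The
command-line wrapper (`inst/scripts/bundlescan.R`, or `cliMain()`
in-process) ties simulation, detection, and validation into a
reproducible workflow with YAML configuration and per-run JSON summaries.

## A small worked run

```{r example, eval = FALSE}
cfg <- SimulationConfig(nRows = 8, nCols = 8, nRepeats = 25,
                        grid = defaultAmplitudeGrid(20, aMin = 0.2),
                        thresholdIndexRange = c(6L, 14L), seed = 7L)
sim <- simulateScan(cfg)
th <- runDetection(sim$scan, DetectionConfig(pValue = 0.05))
compareThresholds(th, truthThresholds(sim$truth))
```
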