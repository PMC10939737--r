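---
title: "Models and methods behind acxplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acxplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acxplast)
```

`acxplast` implements the analysis chain used to study how neuromodulation
reshapes auditory cortex (ACx) in mice, across three read-outs: sound-evoked
adenosine release (SEAR) measured with fast-scan cyclic voltammetry (FSCV)
or fluorescent adenosine sensors, tone-evoked calcium responses of layer 3/4
neurons and their tuning-frequency (TF) plasticity, and frequency
discrimination measured behaviourally through prepulse inhibition (PPI) of
the acoustic startle response. Because the underlying animal recordings are
not publicly deposited, each pipeline ships with a seeded synthetic-data
generator that carries a hidden ground truth; every estimator in the package
is validated by parameter recovery against that truth.

## The SEAR voltammetry model

An FSCV session applies a triangular potential sweep (-0.4 V to 1.5 V and
back at 400 V/s) every 100 ms and records the current at each sample of the
sweep, giving a scan-by-sample matrix. Adenosine oxidation produces current
around 1.4 V on the ascending sweep, so a single time series (the
"oxidation channel") summarizes adenosine dynamics.

The analysis stages follow standard FSCV practice:

* **Background subtraction** — for each stimulus, the mean of the 10 scans
  immediately preceding its onset is subtracted from all scans in that
  stimulus's analysis window. The window runs from the first background scan
  to `onset + duration + 10 s`; how a "peak window" should end for long
  sounds is not defined by the protocol we emulate, so the 10-s tail is a
  configurable default.
* **Oxidation-channel extraction** — the ascending-sweep sample nearest
  1.4 V. At the default 20-kHz digitization the sweep step is 0.02 V and
  1.4 V falls exactly on a sample, making the mapping unique by
  construction.
* **Calibration** — replicate peak currents at known concentrations
  (0.1–5 µM, three replicates each) are averaged and fitted with ordinary
  least squares; the line converts currents to concentrations.
* **Transient metrics** — detection is the first post-onset crossing of
  `baseline mean + 3 SD` (1-s pre-onset baseline); latency is the
  interpolated crossing time minus the onset; rise is the 10–90% time on
  the ascending limb and decay the 90–10% time on the descending limb. The
  10–90 convention is our choice (the source protocol does not state one)
  and both the threshold multiplier and the windows are configurable.

### The synthetic transient kernel

The published kinetics are observables — 10–90% rise from 1.07 s (100-ms
sounds) to 2.55 s (5-s sounds), 90–10% decay from 2.41 s to 6.78 s — not
time constants. A difference of two exponentials, the usual first guess for
a transient, cannot reproduce them: that family's decay/rise ratio is
bounded below by about 5.89 (reached in the alpha-function limit), while the
published pairs have ratios of 2.25 and 2.66. The generator therefore uses a
unit-peak gamma pulse

$$k(t) = (t/t_p)^a \, e^{a(1 - t/t_p)},$$

whose shape $a$ and peak time $t_p$ are solved numerically
(`solve_pulse_shape()`) so that the pulse's 10–90% rise and 90–10% decay
match the targets exactly; this family spans every decay/rise ratio above 1.
Kinetics at intermediate sound durations are log-interpolated between the
100-ms and 5-s anchors.

**Latency convention.** Latency is operationally defined by threshold
crossing, and a gamma pulse has a soft foot: the time between "the pulse
leaves zero" and "the pulse crosses a 3-SD threshold" is large and depends
on the noise level. The generator therefore anchors each transient so that
its crossing of `3 x noise_sd` above baseline occurs at `onset + latency`
(per-trial latency drawn from a normal with mean 0.44 s and SD 0.17 s).
With zero noise the anchor degenerates to the pulse foot. This makes the
generator's latency the same observable the analysis measures, rather than
an unobservable nominal pulse start.

**Amplitude law.** The source data show amplitude growing with sound
duration and intensity but publish no functional form. We use the separable
law `peak = base * (1 + 0.5 log10(dur/0.1 s)) * (1 - 0.5 attn/40 dB)`,
which is monotone in both arguments over the tested ranges; both gains are
parameters. Pairing-epoch stimuli are scaled by a reduction factor whose
default, 0.415, reproduces the 58.5% pairing-induced SEAR reduction of the
electrical-stimulation condition.

**Noise.** Additive Gaussian noise on every matrix element (SD 0.02 nA by
default against a ~1–1.9 nA transient). FSCV baselines drift and flicker in
ways this does not capture; passing recovery tests on this generator shows
the estimators are correct, not that they are robust to electrode drift.

### Pairing reduction and delay dependence

`pairing_reduction()` normalizes per-trial peak amplitudes to the
baseline-epoch mean (100%) and reports `100 - mean(pairing epoch)`. Across
recordings the baseline and pairing means are compared with a two-tailed
paired t test when the paired differences pass Shapiro–Wilk normality at
$\alpha = 0.05$, otherwise a Wilcoxon signed-rank test — mirroring the mixed
use of both tests in this literature.

The dependence of the reduction on the sound–stimulation delay is fitted
with a five-parameter pseudo-Voigt dip,

$$f(\Delta t) = c - A\,[\eta L(\Delta t; \mu, w) + (1-\eta) G(\Delta t; \mu, w)],$$

with unit-peak Lorentzian and Gaussian sharing one centre and one
half-width — the standard five-parameter pseudo-Voigt. Fitting is
Levenberg–Marquardt with deterministic multi-start ($\eta \in \{0, 0.5,
1\}$, three width scales, centre from the data argmin); bounds keep
$w > 0$ and $\eta \in [0,1]$. Multi-start matters: from a poor width guess
the optimizer can park $\eta$ at the wrong boundary.

## The calcium-imaging model

Tone-mapping sessions present a frequency x attenuation grid (default: 8
log-spaced frequencies 4.8–29.4 kHz including the 9.8/13.9/16.4/19.6-kHz
tones used in pairing protocols; attenuations 0/30/60 dB; 75 repeats per
combination = 1800 tones at 1 Hz) while imaging at 10 frames/s.

* **dF/F** — per ROI, `F0` is the 20th percentile of the ROI's own trace (a
  robust baseline for sparse transients; the percentile is configurable),
  and dF/F = `(F - F0)/F0 * 100`.
* **Peak detection** — all strict local maxima above a threshold (default
  10% dF/F) whose interpolated 10–90% rise is at most 0.3 s and whose
  90–10% decay lies in 0.1–2 s, i.e. fast-indicator-like kinetics; others
  are discarded.
* **200-ms rule** — a peak is sound-related only if it falls within 200 ms
  after a tone onset; such peaks are assigned to the nearest preceding
  trial, all others are excluded and logged.
* **Tuning** — each ROI's response matrix is the mean assigned-event
  amplitude per combination over the full declared repeat count, with
  event-less trials contributing zero so the denominator is fixed at 75.
  The TF is the frequency with the largest across-attenuation mean
  response; exact ties break to the lower frequency. An alternative
  "full-trace mean per combination" response measure was considered and
  not implemented: with a fixed-denominator event-amplitude average the
  two differ only by the baseline occupancy of the window, and the event
  route is the one the peak-detection contract defines.
* **Responsiveness** — the protocol we emulate reports that ~18% of neurons
  are tone-responsive but not the criterion used. We gate on a within-ROI
  null: the ROI's event times are circularly shifted against the trial
  schedule (20 deterministic offsets), reassigned and re-tabulated; the ROI
  is responsive when some observed cell exceeds the null mean + 3 null SD.
* **Saturation** — an indicator-saturated cell is pinned at the top of its
  own dynamic range, so ROIs with more than 1% of frames within 0.1% of
  their own maximum are rejected.

The generator gives each responsive neuron (Bernoulli 0.18) a TF on the
stimulus grid, a Gaussian tuning curve in octave space (width 0.5 octaves),
amplitude shrinking linearly to half at 60-dB attenuation, lognormal
trial-to-trial amplitude jitter (SD(log) 0.25), a difference-of-exponentials
indicator kernel (rise 20 ms, decay 350 ms — here the time constants are
given directly and their ratio is large, so this family is appropriate), and
additive Gaussian baseline noise (2% dF/F against 50% responses). It does
not model neuropil contamination, motion, photobleaching or overlapping
ROIs; recovery results certify the estimators, not robustness to those
artifacts.

## Tuning-plasticity statistics

For neurons with a TF in both sessions, the shift statistic is
$\Delta TF = |TF_{before} - f_{pair}| - |TF_{after} - f_{pair}|$ — positive
when tuning moves toward the paired tone. Inference uses:

* a two-sided **Wilcoxon signed-rank test** against median zero. Zeros are
  dropped (the classical convention; the count is logged) — the emulated
  protocol does not state its zero handling. Exact p-values via the
  signed-rank distribution for n <= 25 without ties; otherwise a normal
  approximation with tie correction and continuity correction. Grid-valued
  TFs make ties ubiquitous, so the approximation is the common path.
* the **two-sample Kolmogorov–Smirnov test** on cumulative TF
  distributions, with D computed as an explicit supremum over pooled
  thresholds and an asymptotic p-value (approximate under ties).
* a **transition heatmap**: row-normalized percentages from pre-TF bins to
  post-TF bins over the stimulus grid itself (TFs are grid-valued by
  construction); no TF change puts 100% on the diagonal.

Calibration and power are established on a TF-level generator
(`generate_plasticity_experiment()`): each neuron's measured TF adds
independent one-step grid jitter in both sessions, so under the no-shift
null the (before, after) pair is exchangeable and $\Delta TF$ is symmetric
about zero — the test's level is then meaningful. A configurable fraction
of neurons moves 1–2 grid steps toward the pairing tone in the "after"
session. With 450 matched neurons (three ~150-neuron fields), the null
rejects at ~5% and a 40% shift is detected at p < 0.001 in essentially
every replicate. Neurons responsive in only one session are excluded and
counted; per-animal mixed-effects modelling is out of scope (pooled
neurons, as in the protocols emulated).

## PPI and the frequency-discrimination threshold

A session has four blocks: acclimation, startle-only, a pseudo-random mix
of prepulse trials (each of 0/1/2/4/8/16/32% below the 16.4-kHz background,
10 repeats) with 10 interleaved startle-only trials, and a final
startle-only block for habituation. PPI is
`(1 - prepulse startle / startle-only startle) * 100` with the interleaved
block-3 startle-only mean as the reference (which block supplies the
reference is configurable; interleaved controls are the default because
they share the session state). Negative PPI (facilitation) is retained.

The psychometric curve is a three-parameter logistic in log frequency
difference with the floor fixed at zero,

$$PPI(\Delta f) = \frac{PPI_{max}}{1 + e^{-b(\log \Delta f - \log m)}},$$

fitted to the mean PPI at each positive $\Delta f$ (Levenberg–Marquardt,
deterministic multi-start over grid midpoints and three slopes). The
frequency-discrimination threshold (FDT) is the $\Delta f$ at 50% of total
PPI — the midpoint $m$ by construction. Fits with $r^2 < 0.7$ are excluded,
as are non-convergent fits. Raw PPI is used for fitting; normalization by
the fitted asymptote is display-only.

The generator draws startle magnitudes as
`startle_mean * (1 - inhibition) * lognormal` — multiplicative lognormal
noise because startle forces are positive and right-skewed; the emulated
protocol does not publish its noise distribution, so this is an explicit
assumption. The default CV is 0.15, the noise level at which the
means-based logistic fit attains a median absolute FDT error below one
percentage point over 200 sessions — the recovery precision this package
treats as its design target — while staying within the range reported for
rodent startle variability. True FDT defaults to 8% with a 60% PPI ceiling
and unit slope-scale 2 in natural-log units.

## Orchestration and determinism

`run_end_to_end()` simulates every enabled modality from one master seed
(each modality derives its own stream, so enabling one never perturbs
another), runs the matching pipeline and writes a JSON report plus CSV
tables; two runs with the same configuration are byte-identical. All
generators restore the caller's RNG state.

Problem sizes used in the shipped validation: 200-neuron imaging sessions
with the full 75-repeat grid; 100–200 replicate voltammetry or startle
sessions per recovery estimate; 200 null and 100 shifted plasticity
experiments of 450 neurons. These sizes put Monte-Carlo error comfortably
below each quantity's acceptance band.

## Known limitations

* The voltammetry generator has a stable background; electrode drift,
  pH transients and motion artifacts are absent, so background subtraction
  is easier here than on real electrodes.
* The imaging generator is event-clean: no neuropil, motion or bleaching.
  ROI identity across sessions is exact by construction; spatial matching
  of real fields is out of scope.
* KS and signed-rank p-values on grid-valued TFs are approximate under
  ties; the package reports the tie-corrected normal approximation.
* The pseudo-Voigt fit assumes a single shared width; asymmetric delay
  windows (e.g. much denser sampling on one side) can bias $\mu$ slightly.
* Behavioural sessions model only magnitude noise; sensorimotor gating
  drift within a session (habituation affecting block 3) is not simulated,
  although the block-4/block-2 habituation ratio is reported.
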