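# acxplast

Analysis pipelines for three read-outs of auditory-cortex (ACx)
neuromodulation experiments in mice:

1. **Sound-evoked adenosine release (SEAR)** from fast-scan cyclic
   voltammetry (FSCV) or fluorescent adenosine-sensor traces: per-stimulus
   background subtraction, 1.4-V oxidation-channel extraction, flow-cell
   calibration, transient kinetics (latency, 10–90% rise, 90–10% decay),
   pairing-epoch reduction, and pseudo-Voigt fitting of the delay dependence
   of pairing effects.
2. **Tuning-frequency (TF) plasticity** from two-photon calcium imaging:
   dF/F, kinetics-screened peak detection, the 200-ms stimulus-assignment
   rule, frequency x attenuation tuning maps, and pre/post shift statistics
   — ΔTF = |TF_before − f_pair| − |TF_after − f_pair|, Wilcoxon signed-rank,
   two-sample Kolmogorov–Smirnov on cumulative TF distributions, and
   row-normalized ΔTF transition heatmaps.
3. **Perceptual acuity** from prepulse inhibition (PPI) of the acoustic
   startle response: PPI = (1 − prepulse startle / startle-only startle) ×
   100, a 3-parameter logistic psychometric fit in log Δf, the frequency
   discrimination threshold (FDT) at 50% of total PPI, the r² < 0.7
   exclusion rule, and matched pre/post cohort comparisons.

Because the animal recordings this kind of study produces are not publicly
deposited, the package ships seeded synthetic-data generators for all three
modalities. Each generator records its hidden ground truth (transient times
and amplitudes, true TFs and responsive flags, true FDT), and the test suite
validates every estimator by parameter recovery against it. The generators
default to the published study conditions: transient latency 0.44 ± 0.17 s,
rise 1.07–2.55 s and decay 2.41–6.78 s scaled by sound duration, ~18%
tone-responsive neurons over a 4.8–29.4-kHz grid with 75 repeats per
frequency/attenuation combination, and 0–32% prepulse grids with 10 repeats.

## Worked example

Simulate a pairing-protocol voltammetry session (5 baseline, 5 pairing,
5 post stimuli of 5-s broadband noise at 60-s intervals) and analyse it:

```r
library(acxplast)

g <- generate_voltammetry_session(sear_gen_params(), sear_schedule(), seed = 1)
a <- analyze_sear_session(g$session)
head(a$metrics, 6)
#>  stimulus    epoch  peak latency rise_time decay_time
#>         1 baseline 1.893   0.384     2.682      7.050
#>         2 baseline 1.887   0.450     2.568      6.820
#>         3 baseline 1.847   0.148     2.592      6.558
#>         4 baseline 1.847   0.836     2.581      6.798
#>         5 baseline 1.904   0.516     2.746      6.774
#>         6  pairing 0.806   0.220     2.996      6.782
a$pairing$reduction_pct
#> [1] 57.80135
```

Per-stimulus peaks sit near 1.9 nA at baseline with rise/decay close to the
5-s-sound kinetics the generator targets (2.55 s / 6.78 s); pairing-epoch
peaks drop to ~0.8 nA, and the pairing analysis reports a 57.8% reduction —
the generator's default reduction factor reproduces the 58.5% reduction seen
with basal-forebrain pairing (the cohort-level paired test needs three or
more recordings).

A startle session and its psychometric fit:

```r
gp <- generate_ppi_session(ppi_gen_params(), seed = 1)
r <- analyze_ppi_session(gp$session)
c(fdt = r$fdt, max_ppi = r$max_ppi, r2 = r$r2, asr = r$asr)
#>       fdt   max_ppi        r2       asr
#>  8.133224 59.572491  0.993976  1.004762
```

The fitted FDT (8.13%) recovers the generator's true 8% threshold; the fit
would be excluded if r² fell below 0.7.

`run_end_to_end(default_run_config(seed = 1), "out/")` chains all modalities
and writes a JSON report with parameter-recovery summaries plus CSV tables.

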