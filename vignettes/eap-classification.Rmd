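---
title: "Classifying somatic and neuritic extracellular action potentials on high-density microelectrode arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic and neuritic extracellular action potentials on high-density microelectrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eapshape)
```

## The scientific problem

High-density microelectrode arrays (HDMEAs) carry thousands of electrodes at
tens-of-micrometre pitch beneath a neuronal culture. Every electrode records
extracellular action potentials (EAPs), but an EAP can originate from a cell
body, a dendrite, or a distal axon, and these sources produce systematically
different waveforms. Sites near somata record wide spikes — monophasic or
biphasic with a dominant negative trough — while distal neurites (mostly
axons) produce narrow triphasic spikes flanked by positive peaks. This
package implements the complete analysis chain that turns raw multichannel
voltage traces into a per-site somatic/neuritic classification and a
quantitative measure of spike-shape adaptation, together with a synthetic
recording generator that provides ground truth for validating every stage.

## The analysis chain

1. **Detection** (`bandpass`, `estimate_noise_sd`, `detect_events`,
   `activity_map`). Traces are band-pass filtered at 500–3,000 Hz with a
   zero-phase (forward–backward) 2nd-order Butterworth filter; zero phase
   matters because all later alignment is on the trough sample. Events are
   negative threshold crossings at 5 times the background-noise SD, with the
   detector blind for 0.8 ms after each crossing, the event time taken at
   the deepest sample inside the blanking span (earliest sample on ties),
   and a 2.5 ms snippet extracted around the peak. The noise SD is
   `median(|x|)/0.6745`, which is nearly unbiased for Gaussian noise and
   insensitive to spike content. Sites with whole-recording firing rates
   above 0.2 Hz (strict) are flagged active.

2. **Sorting** (`align_and_stack`, `cluster_events`, `accept_units`,
   `oversample`, `footprint`). Sorting runs on three neighbouring
   electrodes; crossings within 0.5 ms across the trio are one
   multi-channel event, aligned on the trough of its largest channel. The
   concatenated snippets are projected onto 10 principal components,
   overclustered by K-means into 8 miniclusters, and miniclusters are merged
   while any pair's normalized interface energy exceeds the 0.001 stop
   criterion (energies recomputed after every merge). Units are accepted
   when their refractory-period-violation fraction (1.5 ms floor) is below
   0.01 and they carry at least 100 spikes — a codified, reproducible form
   of what is classically a manual cluster-quality review. Footprints are
   spike-triggered averages of the wideband traces on every electrode of
   the block, oversampled to 320 kHz; the representative electrode is the
   one with the deepest STA trough.

3. **Features** (`waveform_features`). Four features of the averaged spike:
   signed trough amplitude (µV); half-width — the contiguous time below 50%
   of the trough, with the crossings located by linear interpolation;
   trough–peak width — time from the trough to the first positive local
   maximum after it (at least 5% of the trough depth, so noise ripples do
   not qualify; monophasic spikes return `NA`); and RSTD — the per-sample
   SD of the snippets normalized by the mean waveform's peak-to-peak
   amplitude, averaged over samples. The mean-over-samples reduction is a
   deliberate choice: it is bounded, stable, and makes the iid-noise
   expectation exactly `sd_noise / peak_to_peak`.

4. **Classification** (`screen_features`, `match_template`,
   `distance_label`, `population_summary`). Records pass screening when the
   averaged spike reaches 100 µV (inclusive), RSTD is below 1 (strict), and
   more than 100 spikes contribute (strict). Screened waveforms are
   peak-to-peak normalized and scored against the four canonical templates
   by normalized cross-correlation maximized over lags within ±0.25 ms;
   the highest score assigns the type (ties to the lower index, with a
   warning). Types 1–2 are the somatic class, 3–4 the neuritic class.
   Independently, a site is labelled somatic when its representative
   electrode lies strictly within 50 µm of a listed soma, neuritic
   otherwise (an empty soma table means neuritic).

5. **Adaptation** (`continuous_firing_rate`, `fit_adaptation`,
   `compare_groups`). The continuous firing rate is the recursion
   `cFR(t) = d·cFR(t−Δt) + (1−d)/Δt` with `d = exp(−Δt/τ)`, τ = 100 ms,
   initialised at 0 Hz for the first spike (which is excluded from
   fitting). Per-spike features against cFR are fitted with
   `g(x) = y_c·exp(b·x) + y_inf`, and the adaptation rate is
   `AR = (y_inf/(y_inf + y_c) − 1)·100%`: negative when amplitude shrinks
   at high rates, positive when the spike widens. Amplitudes are fitted as
   magnitudes so the sign convention holds. Group AR distributions are
   compared with two-tailed Mann–Whitney tests.

## The synthetic generator

`make_layout` builds hexagonally packed grids (default pitch 17.8 µm);
`make_template_waveform` produces the four canonical shapes as sums of
Gaussian lobes — one unit-depth negative lobe plus zero to two positive
lobes. Lobe geometry is calibrated so the closed-form features hit the
class medians: somatic half-width 250 µs (trough σ = 106.16 µs), neuritic
130 µs (σ = 55.20 µs), trough–peak offsets 900 µs (type 2) and 420 µs
(types 3–4). Because every positive lobe sits several of its own widths
away from the trough, the summed waveform's features match each lobe's
closed form to well under one 320 kHz sample.

`make_spike_train` is a two-level point process: Poisson burst onsets, a
fixed number of spikes per burst, and intra-burst intervals drawn as a
2 ms absolute dead time plus an exponential tail with the requested mean
rate. The dead time is deliberate: a plain exponential at 100 Hz would put
~14% of intervals under the 1.5 ms refractory floor, so genuine single
units would be indistinguishable from contaminated clusters — real neurons
do not do that, and neither does the generator.

`render_recording` adds each spike to every electrode scaled by
`exp(−d/λ)` with λ = 25 µm by default, placing the signal near zero beyond
~100 µm, consistent with how far extracellular electrodes can sense a
cell. Per spike, amplitude and width are scaled by `g(cFR)/g(0)` using the
unit's adaptation parameters, so bursts carry shrinking, widening spikes
exactly as the adaptation model assumes. Gaussian noise (default SD 10 µV
before filtering) is band-limited to 25 Hz–3.5 kHz, emulating an on-chip
acquisition filter, and added to the clean spike signal. The noise — not
the spike waveform — is filtered: the generator's contract is that a unit
sitting on an electrode renders its exact trough depth there, which a
3.5 kHz low-pass would break for the narrow neuritic shapes. Consequently
rendered spike shapes are the canonical templates themselves, and the
analysis chain's recovery of their features is a genuine round-trip check
rather than a deconvolution problem.

Default unit amplitudes are 200/180 µV (somatic types 1–2) and 120/110 µV
(neuritic types 3–4) at the origin electrode. The neuritic values sit at
the top of the range typical of axonal recordings rather than at the
neuritic population median (which lies below the 100 µV screening bar):
ground-truth-recovery experiments need units that the screening stage is
meant to keep. Default adaptation parameters (as multipliers with
`g(0) = 1`): somatic amplitude `y_c = 0.30, b = −0.05/Hz, y_inf = 0.70`
(AR −30%) with width `(−0.15, −0.05, 1.15)` (AR +15%); type 3 mild
(amplitude AR −10%); type 4 none — mirroring the qualitative ordering in
which somatic spikes adapt strongly and distal axonal spikes barely at
all.

## Numerical and design choices

- **Interface-energy kernel.** Cluster aggregation uses Gaussian
  similarities `exp(−d²/(2h²))` with `h` set to half the median
  nearest-neighbour distance in PC space. The kernel must separate two
  regimes at the same 0.001 criterion: partitions of one unimodal cloud
  (connection ~0.1–0.5, must merge) and genuinely distinct clusters at
  ~10× the within-cluster spread (must not merge). A heavier-tailed
  exponential kernel at the median-NN scale leaves the second regime near
  0.02–0.08 — above the criterion — so distinct units would merge; the
  Gaussian kernel at half that scale puts them five orders of magnitude
  apart.
- **Adaptation-fit identifiability.** As `b → 0` the exponential term is
  collinear with the intercept, and the asymptote `y_inf` (hence AR)
  becomes arbitrary: on truly rate-independent features the unconstrained
  fit happily reports AR of −20% or worse from noise. Two guards apply:
  `b` is bounded so the exponential decays at least twofold across twice
  the observed cFR range, and the exponential must beat the constant model
  in an F-test at p < 0.01, otherwise the feature is reported as
  rate-independent with AR = 0. The multi-start (5 geometric starts of `b`
  scaled to the cFR range) takes the best-RSS converged fit.
- **STA computation.** Averaging and band-limited interpolation are both
  linear, and spike times are at acquisition-sample resolution, so the
  footprint STA is computed at 20 kHz and Fourier-oversampled once to
  320 kHz — identical to oversampling every snippet first, at a fraction
  of the cost. Oversampling is exact on the original sample grid.
- **Degenerate inputs.** Zero detected events give valid empty tables;
  blocks with no active electrode, too few trio events, or no accepted
  unit return a structured empty result with the drop reason logged;
  snippet windows truncated by a recording edge are discarded; template
  score ties go to the lower type index with a warning; AR is flagged
  missing when `|y_inf + y_c| < 1e-9`.
- **cFR fixed point.** For constant inter-spike interval Δt the recursion
  converges to exactly 1/Δt, which the tests use as an analytic oracle,
  along with the hand-evaluated two-spike case.

## What the validation shows — and what it does not

The test suite validates every stage against closed forms (Gaussian FWHM,
lobe offsets, RSTD expectations, the cFR fixed point, exact small-sample
Mann–Whitney p-values) and the whole chain against ground truth: a
30-block population with a deterministic 80/20 somatic/neuritic
composition, one unit per 3×3-electrode block, 60 s at 20 kHz per block
(~300 burst-structured spikes), is recovered with the correct somatic
fraction (±5 percentage points), correctly ordered adaptation (somatic
median AR more negative than neuritic, Mann–Whitney p < 0.01), and
injected AR recovered within ±5 points at ~600 spikes under 2% noise.
These problem sizes are the package's validation defaults; larger
simulations only tighten the same estimates.

The generator emulates the statistical structure the analysis assumes —
canonical shapes, exponential spatial decay, burst trains, band-limited
Gaussian noise — and deliberately omits biophysical forward modelling
(cable equations, line sources), electrode impedance variation, drift,
overlapping spikes from co-active neighbouring units, and non-stationary
noise. Passing tests therefore demonstrate that the chain is correct and
self-consistent under its own assumptions, not that those assumptions
exhaust real HDMEA data. In particular, real somata within 50 µm of an
active axon produce genuinely mislabelled sites (the distance rule is a
proxy, not truth), and measured templates can replace the canonical set
via `read_templates` wherever classification is performed.

## Known limitations

- Thresholds are fixed per recording; no adaptive or time-varying
  detection.
- Template assignment is hard (argmax); no soft/probabilistic scores
  beyond the per-type cross-correlations.
- The adaptation model is a single exponential in cFR; bi-exponential or
  spike-history-kernel alternatives are out of scope.
- Sorting assumes the three-electrode configuration and does not attempt
  deconvolution of temporally overlapping spikes.
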