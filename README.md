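# eapshape

Somatic vs. neuritic classification of extracellular action potentials
(EAPs) recorded with high-density microelectrode arrays (HDMEAs), with
quantification of firing-rate-dependent spike-shape adaptation.

## What it is for

HDMEAs record extracellular spikes at thousands of sites under a neuronal
culture, but a threshold-crossing event may originate from a cell body or
from a distal neurite (usually an axon). The two sources produce
systematically different waveforms: somatic EAPs are wide — monophasic or
biphasic with a dominant negative trough — while neuritic EAPs are narrow
and triphasic. `eapshape` implements the full analysis chain that tells
them apart, for electrophysiologists working with planar
microelectrode-array recordings:

- threshold-crossing spike detection (500–3,000 Hz zero-phase band-pass,
  5σ threshold on a robust `median(|x|)/0.6745` noise estimate, 0.8 ms
  blanking) and per-electrode firing-rate activity maps (0.2 Hz cut);
- spike sorting on three-electrode groups (PCA → K-means overclustering →
  interface-energy aggregation, stop criterion 0.001), acceptance of
  units with refractory-period-violation fraction < 0.01 and ≥ 100 spikes;
- spike-triggered-average footprints from wideband traces oversampled to
  320 kHz, with the representative electrode at the deepest trough;
- waveform features: amplitude, half-width, trough–peak width, RSTD;
- screening (≥ 100 µV, RSTD < 1, > 100 spikes), cross-correlation
  template matching against four canonical types (1–2 somatic, 3–4
  neuritic), and the 50 µm soma-distance rule;
- spike-shape adaptation: the continuous firing rate
  `cFR(t) = d·cFR(t−Δt) + (1−d)/Δt`, `d = e^{−Δt/τ}`, τ = 100 ms; the
  exponential fit `g(x) = y_c e^{bx} + y_∞` of per-spike features vs cFR;
  the adaptation rate `AR = (y_∞/(y_∞+y_c) − 1)·100%`; and two-tailed
  Mann–Whitney comparisons of AR between template types.

A synthetic HDMEA generator (hexagonal layouts, burst-structured spike
trains, the four canonical waveform shapes, exponential spatial decay,
band-limited noise, injectable adaptation) provides ground truth so the
entire chain is testable without external recordings.

## Worked example

Simulate one recording block — a 3×3 electrode patch at 17.8 µm pitch
with a bursting somatic unit on electrode 3 — and run the full analysis:

```r
library(eapshape)

layout <- make_layout(3, 3, pitch = 17.8)
origin <- c(layout$x[4], layout$y[4])          # electrode id 3
unit   <- make_unit(1, "somatic_type2", origin)
train  <- make_spike_train(60, burst_rate = 1, intra_burst_rate = 100,
                           burst_length = 5, seed = 42)
rec    <- render_recording(layout, list(unit), list(train),
                           noise_sd = 10, duration = 60, seed = 43)

set.seed(1)
res <- analyze_block(rec)
print(res$footprint)
print(res$features)
print(res$classification)
print(res$adaptation$amplitude)
```

```
EAP footprint: 9 electrodes, 347 spikes averaged, rep. electrode 3 (peak -147.5 uV)
  amplitude_uV half_width_us trough_peak_width_us      rstd n_spikes
1     -147.538       272.835                  975 0.0362955      347
  assigned_type   score_1   score_2   score_3   score_4 source_class
1             2 0.9265873 0.9940588 0.6245809 0.6571986      somatic
Spike-shape adaptation fit: amplitude (n = 346 spikes)
  g(x) = y_c * exp(b x) + y_inf
  y_c = 55.75   b = -0.04986 /Hz   y_inf = 125.4   (RSS 9621)
  adaptation rate AR = -30.78%
```

Reading the output: all 347 spikes of the unit were detected, sorted into
one clean cluster and averaged; the representative electrode is the one
the unit sits on. The averaged spike reaches −147.5 µV (the 180 µV source
amplitude, reduced by within-burst adaptation averaged into the STA), its
half-width and trough–peak width sit at the wide somatic values, and the
low RSTD (0.036) marks a well-isolated single unit. Template matching
assigns type 2 (biphasic somatic, score 0.994) — the somatic class. The
amplitude-vs-cFR fit recovers the −30% amplitude adaptation injected by
the generator (AR = −30.8%): during bursts this unit's spikes shrink by
about a third, the behaviour typical of somatic sources, while distal
axonal sources show little to no adaptation.

`simulate_population_study()` scales this to a labelled population of
blocks and `run_pipeline()` drives the chain over recordings stored in
the package's trace container (see `write_traces`/`read_traces`). A thin
command-line driver with `simulate` and `run` subcommands is installed at
`inst/cli/eapshape.R`.

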