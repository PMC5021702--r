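Package: eapshape
Title: Classification of Somatic and Neuritic Extracellular Action
    Potentials from High-Density Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects extracellular action potentials (EAPs) in
    high-density microelectrode-array (HDMEA) recordings, sorts them into
    single units, extracts spike-triggered-average footprints and
    waveform-shape features (amplitude, half-width, trough-peak width,
    relative standard deviation), classifies recording sites as somatic or
    neuritic by cross-correlation template matching and a soma-distance
    rule, and quantifies firing-rate-dependent spike-shape adaptation via
    a continuous-firing-rate recursion and exponential feature fits.
    Includes a synthetic HDMEA recording generator (hexagonal electrode
    layouts, burst-structured spike trains, four canonical waveform types,
    spatially decaying footprints, band-limited noise) so the full
    analysis chain can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
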