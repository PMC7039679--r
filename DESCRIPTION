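Package: patchkit
Title: Patch-Clamp Sweep Analysis for Intrinsic, Synaptic, and Network Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for slice electrophysiology recordings of
    hippocampal interneurons and pyramidal cells. Extracts intrinsic membrane
    and action-potential properties (input resistance, membrane time constant,
    sag index, spike threshold at the 10 mV/ms slope criterion, half-width,
    afterhyperpolarization, adaptation ratio) from current-clamp step families;
    summarises unitary synaptic transmission (amplitude, potency, failure rate,
    paired-pulse ratio, coefficient of variation, latency, kinetics) from
    voltage-clamp traces; dissociates GABAergic and glutamatergic components by
    driving-force polarity with Nernst reversal potentials and conductance
    conversion; estimates quantal release-rate histograms by FFT deconvolution
    against a 20 pA miniature-IPSC kernel, with per-pulse synchronous and
    asynchronous release and synchronicity ratios; and computes gamma-band
    (20-80 Hz) Welch power spectra of local field potentials. Includes seeded
    synthetic-trace generators with full ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
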