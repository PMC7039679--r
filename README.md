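# patchkit

Quantification toolkit for slice patch-clamp electrophysiology, written for
the analysis chain used in studies of hippocampal CCK+ interneurons and
their GABA/glutamate co-releasing synapses onto pyramidal cells. The package
covers four stages that usually live in ad-hoc lab scripts, and pairs each
one with a seeded synthetic-trace generator carrying full ground truth, so
every estimator is testable by parameter recovery.

## What it computes

**Intrinsic membrane and action-potential properties** from current-clamp
step families:

- input resistance `R_m` by linear regression of steady-state voltage
  deflections (mean of the last 200 ms of each 2 s step) against injected
  current, restricted to steps within ±15 mV of rest;
- membrane time constant `τ_m` by single-exponential fit
  `V(t) = V0 + ΔV(1 − e^{−t/τ})` to the average of repeated −20 pA / 400 ms
  pulses, with `C_m = τ_m / R_m`;
- sag index `(V_rest − V_sag) / (V_rest − V_hyp)` interpolated via
  polynomial V–I fits to the current where `V_sag = −80 mV` (Ih rebound
  measure);
- spike threshold at the upward `dV/dt = 10 mV/ms` crossing, amplitude,
  half-width at half amplitude (sub-sample interpolation),
  afterhyperpolarization depth, maximal rise/decay slopes, firing frequency,
  and the adaptation ratio (mean of the last 2–3 interspike intervals over
  the first).

**Unitary synaptic transmission** from voltage-clamp trains: per-trial
pulse-locked peak measurement with a noise-SD failure criterion; amplitude
(including failures), potency (excluding them), failure rate,
coefficient of variation, 50 Hz paired-pulse ratio, latency, 20–80% rise
time and decay τ; Nernst reversal potentials from pipette/bath salt
compositions; conductance conversion `G = I_peak/(V_hold − E_rev)`;
polarity-based dissociation of GABAergic (outward above E_Cl) versus
glutamatergic (inward) components; and DSI suppression
`100·(1 − I_DSI/I_ctl)`.

**Quantal release rates by FFT deconvolution**: an artificial miniature
IPSC (bi-exponential, scaled to exactly 20 pA) is divided point-by-point
into the spectrum of the smoothed postsynaptic train (50 passes of
(¼, ½, ¼) binomial smoothing), yielding a release-rate histogram in
quanta/s. Per pulse, synchronous release is the area in the 5 ms bin after
the step onset and asynchronous release the area in the 15 ms bin before
the next onset; their quotient is the synchronicity ratio (SR), which
declines along trains with progressively desynchronizing release.

**Gamma-band field potentials**: Welch power spectra (1 s Hann segments,
50% overlap) of 10 s LFP epochs, with peak frequency, peak power,
integrated 20–80 Hz band power, and before/during/after illumination
modulation ratios.

## Worked example

```r
library(patchkit)

# chloride reversal of the K-gluconate internal against recording aCSF
nernst(solution_kgluconate_internal(), solution_acsf(),
       ion = "Cl", z = -1, temperature = 33)
#> [1] -67.39019

# simulate a passive step family from known ground truth and recover Rm
fam <- gen_passive_steps(c(-20, -15, -10, -5, 5, 10, 15, 20),
                         r_m = 158.5, c_m = 131.2, v_rest = -56.9,
                         noise_sd = 0.3, seed = 1)
input_resistance(fam$sweeps)
#> Input resistance: 158.5 MOhm (8/8 steps within the linear range)

# an accommodating spike train with exactly controlled waveform geometry
train <- gen_ap_train(c(50, rep(21.5, 9)), threshold = -41.9,
                      amplitude = 57.4, half_width = 0.74, ahp = 10.3)
spikes <- detect_spikes(train$sweep)
ap_features(train$sweep, spikes, which = 1)
#> # A tibble: 1 x 6
#>   threshold amplitude half_width max_rise max_decay   ahp
#>       <dbl>     <dbl>      <dbl>    <dbl>     <dbl> <dbl>
#> 1     -41.9      57.4      0.739     224.     -121.  10.3
train_stats(spikes)
#> # A tibble: 1 x 3
#>   n_spikes firing_frequency adaptation_ratio
#>      <int>            <dbl>            <dbl>
#> 1       11             13.8             0.43
```

The tibbles read directly as the conventional intrinsic-parameter table:
threshold in mV, half-width in ms, slopes in mV/ms, and the adaptation
ratio as late-ISI mean over first ISI. A single call to
`run_pipeline(default_config(seed = 1), "out/")` executes all four stages
end to end and writes one CSV per result table plus a manifest with the
seed, configuration, and output checksums; identical configurations give
byte-identical bundles.

`membrane_properties()`, `unitary_stats()`, `deconvolve_train()` and
`power_spectrum()` return tibbles or tidy-able objects (`tidy()`,
`glance()`, `autoplot()`), so results chain straight into dplyr/ggplot2.

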