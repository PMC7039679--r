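---
title: "patchkit: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{patchkit: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchkit)
```

patchkit implements the quantitative chain of a slice electrophysiology
study of hippocampal CCK+ interneurons: intrinsic membrane and
action-potential properties, unitary synaptic event statistics, GABA versus
glutamate dissociation by driving-force polarity, quantal release-rate
estimation by FFT deconvolution, and gamma-band spectral summaries. This
vignette explains the underlying models, the estimators and their numerical
choices, what the synthetic generators do and do not emulate, and the
package's known limitations.

## Data model and units

A `sweep_trace()` is one uniformly sampled trace plus metadata: sampling
interval `dt` (seconds; 5e-5 for the conventional 20 kHz), clamp mode
(which fixes the units — mV in current clamp and field mode, pA in voltage
clamp), holding level, and an optional stimulus protocol. Time is in
seconds everywhere inside the package; inward currents are negative and
outward currents positive throughout. Unit conversions happen only at the
I/O boundary: the native interchange format is a diffable text file
(`key: value` header, one tab-separated sample column per sweep) that
round-trips to full double precision, written and read by
`write_recording()` / `read_recording()`. No resampling or software
filtering is applied on read: analyses operate on the trace as recorded
(acquisition-side anti-alias filtering is assumed).

## Intrinsic properties

**Input resistance.** The steady-state deflection of each 2 s current step
(mean of the last 200 ms, relative to the pre-step baseline) is regressed
on injected current by ordinary least squares; the slope in mV/pA is the
resistance in GΩ. Steps deflecting the membrane more than 15 mV from rest
are excluded before fitting, keeping the estimate inside the linear range;
at least three qualifying steps are required. The last-200 ms steady-state
window is the same one used for the sag analysis, adopted for consistency.

**Membrane time constant.** Repeated identical hyperpolarizing pulses
(conventionally twenty −20 pA, 400 ms pulses) are averaged and fit with a
single exponential `V(t) = V0 + ΔV(1 − e^{−t/τ})` by Levenberg–Marquardt
least squares over the window from pulse onset to five initial-guess time
constants. Fits outside (0.5, 200) ms are rejected as non-physiological.
Capacitance is derived as `C_m = τ_m / R_m`; the package deliberately has
no independent capacitance estimator, so a table value obtained by a
different (unspecified) method need not match the `τ/R` quotient exactly.

**Sag index.** For each hyperpolarizing step two voltages are measured:
the peak deflection `V_hyp` and the steady state `V_sag` (last 200 ms).
Both are fit against current with cubic polynomials (quadratic with fewer
than five steps), the current `I*` solving `V_sag(I*) = −80 mV` is found by
root search strictly inside the sampled range — the function refuses to
extrapolate — and the index `(V_rest − V_sag(I*)) / (V_rest − V_hyp(I*))`
is reported. One numerical choice matters here: `V_hyp` is the mean over a
short (5 ms) window centred on the trace minimum rather than the
single-sample minimum. The minimum of a noisy trace is biased downward by
extreme-value statistics (about 0.7 mV at 0.2 mV noise over a 1 s step),
which alone would bias the index by roughly 0.02; the windowed mean removes
this bias and converges to the true minimum as noise vanishes.

**Spikes.** A spike onset is an upward crossing of `dV/dt = 10 mV/ms`
(central differences on the raw trace; crossing time and voltage linearly
interpolated between samples) followed within 2 ms by a local maximum at
least 20 mV above the onset voltage; onsets within 1 ms of the previous
accepted onset are ignored. Threshold is the onset voltage, amplitude the
peak minus threshold, half-width the interpolated interval between the two
crossings of threshold + amplitude/2, and the AHP the depth of the
post-spike trough below threshold (searched 20 ms past the peak or up to
the next onset; truncated searches return `NA`). The adaptation ratio is
the mean of the last interspike intervals over the first — last three when
at least five exist, last two with three or four, the single last with two.
This tie-break makes an ambiguous "last 2–3" rule deterministic.

## Unitary synaptic statistics

`measure_events()` measures, for every presynaptic pulse, the
baseline-subtracted extremum in the response window (15 ms default),
flags the trial as a transmission failure when the peak does not exceed
three baseline-noise standard deviations, and records failure amplitudes
as zero. Consequently *amplitude* (mean over all trials) equals *potency*
(mean over successes) times the success rate by construction — an identity
the tests assert. The CV is the sample (n−1) SD over mean of first-pulse
amplitudes with failures included, the PPR the mean second-pulse over mean
first-pulse amplitude, and latency the pulse-to-10%-of-peak interval.

Peaks are picked on a lightly smoothed copy of the trace (20 binomial
passes, a ~0.16 ms Gaussian blur at 20 kHz) with the noise SD estimated on
the same smoothed baseline. This matters for the failure criterion: the
raw extremum of white noise over a multi-millisecond window sits near 3 SD
by extreme-value statistics, which would systematically misclassify
failures. Even smoothed, a k = 3 criterion retains a few percent
false-event rate per window under white noise — an intrinsic property of
the windowed-extremum statistic, worth remembering when failure rates from
noisy recordings look slightly low. The criterion multiplier and smoothing
are configurable.

Reversal potentials come from `nernst()`, which sums an ion's total
concentration across the salts of each solution (e.g. 5 KCl + 3 MgCl₂
gives 11 mM chloride) and evaluates `(RT/zF)·ln([out]/[in])`. For the
built-in potassium-gluconate internal against the recording aCSF this
yields −67 mV for chloride at 33 °C. Conductance conversion
`G = I/(V_hold − E_rev)` refuses driving forces under 5 mV and flags
sign-inconsistent inputs as mis-assigned components.
`split_components()` exploits the polarity dissociation: held between the
two reversals, GABAergic currents are outward and glutamatergic currents
inward. With overlapping kinetics the fast inward component can be masked
by the rising slow outward one, so quantitative glutamate conductances are
best measured on pharmacologically isolated responses, as in the
pipeline's default protocol.

## Deconvolution and synchronicity

The release-rate estimator models the postsynaptic train as the
convolution of a quantal event waveform with a release-rate function. The
kernel is a bi-exponential with the measured rise and decay kinetics,
scaled so its peak equals exactly 20 pA (`make_kernel()` enforces this on
the sampled grid). The trace is baseline-subtracted, smoothed with 50
passes of the (¼, ½, ¼) binomial kernel, and both signals are zero-padded
to a power of two at least the sum of their lengths — preventing circular
wraparound — before point-by-point spectral division and inverse FFT.

Raw spectral division is ill-posed where the kernel spectrum is tiny, so
magnitudes below `ε = 10⁻³` of the spectral maximum are floored (phase
preserved) before dividing; `ε = 0` reproduces the raw division, and the
pre-smoothing already suppresses most high-frequency content. The output
is scaled to quanta per second — one kernel-worth of charge integrates to
one quantum — so deconvolving the kernel itself yields a unit impulse, and
the total area equals trace charge over kernel charge (both asserted in
tests, along with reconstruction of the smoothed train to under 5%
relative RMS).

`synchronicity()` integrates the rate in the 5 ms bin after each step
onset (synchronous) and the 15 ms bin before the next onset
(asynchronous); at 50 Hz the two bins partition the inter-pulse interval.
The final pulse uses a virtual next onset one period later. Ratios with
asynchronous area below 10⁻³ quanta are `NA` rather than unstable
quotients. `deconvolve_train()` deconvolves each sweep individually but
reports the per-pulse ratio of *mean* areas across sweeps: with only a few
quanta per bin per sweep, per-sweep ratios are dominated by shot noise
(the per-sweep table is still returned for inspection).

## Spectral summaries

`power_spectrum()` is a Welch estimator: 1 s Hann-windowed segments, 50%
overlap, per-segment linear detrend, one-sided densities normalized so the
integral over frequency equals the time-domain variance (Parseval, checked
to 2% in tests). Segment length, overlap, and band edges are configurable
and recorded in the result; the defaults fix 1 Hz resolution, a 10–100 Hz
peak-search band, and inclusive 20–80 Hz gamma band edges. Band power is
emitted both integrated (units²) and as mean density, since published
"power" values are sometimes one and sometimes the other.
`illumination_modulation()` forms during/pre and post/pre ratios of peak
and band power plus the peak-frequency shift, flagging band-power ratios
under 0.05 as suppressed (the residual then reflects the noise floor, not
an oscillation).

## Synthetic generators and what passing tests show

Each generator produces sweeps from explicit ground truth, with all
randomness drawn from per-sweep substreams derived from `(seed, sweep
index)` so extending a family never perturbs existing sweeps.

- `gen_passive_steps()` is an RC membrane (`τ = R_m C_m`) with an optional
  sag factor `(1−g) + g·e^{−t/τ_sag}`; `sag_fraction_for_index()` solves
  for the `g` giving a target true index. Default study conditions follow
  the recording protocol: 20 kHz, 2 s steps in 5 pA increments, 0.2–0.3 mV
  trace noise (typical of whole-cell baselines), sag relaxation τ of
  150 ms.
- `gen_ap_train()` builds piecewise-analytic action potentials — quadratic
  slope-ramp approach crossing 10 mV/ms exactly at the threshold
  parameter, quarter-sine upstroke and cosine downstroke solved so the
  half-amplitude width equals the half-width parameter, sine AHP dip and
  cosine recovery — rather than a conductance-based neuron model. The
  analyses only measure waveform geometry, so exactly controllable
  geometry is what makes threshold/half-width recovery tests meaningful.
- `gen_synaptic_trace()` draws per pulse and component: Bernoulli
  failures, lognormal quantal scale (CV configurable; the latency jitter
  SD of 0.2 ms and quantal CV defaults are conventional values, not
  measured ones), multiplicative depression per preceding success, and
  synchronous (fixed latency + jitter) or asynchronous (uniform in the
  15 ms window before the next pulse) release times; the current is
  `Σ g_i(t)(V_hold − E_i)` with unit-peak bi-exponential conductances. The
  asynchronous fraction grows linearly along the train by default,
  reproducing the declining-synchronicity phenotype.
- `gen_lfp()` is a sinusoid plus white noise at 2 kHz — sufficient for
  20–80 Hz summaries, and deliberately minimal.

Passing recovery tests therefore demonstrate estimator correctness under
known ground truth with white Gaussian noise. They do not establish
robustness to what real recordings add: correlated (filtered) noise,
electrode drift and series-resistance changes, overlapping spontaneous
events, stimulus artifacts, or kinetics that drift within a session.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale chosen to
match the recording protocol: 8-step families of 2 s sweeps at 20 kHz, 20
pulse repeats for the time constant, 6-step sag families, 10–40 trial
trains of 25 pulses at 50 Hz, and 10 s LFP epochs — a few seconds of
compute per stage. `run_pipeline()` executes all stages from one
configuration, writes per-table CSVs plus a manifest (package version,
configuration, seed, output MD5s), and is byte-deterministic under a fixed
seed.

## Known limitations

- No ABF/NWB reader ships with the package; the native text format is the
  interchange, and binary containers must be converted upstream.
- Automatic rheobase search is not implemented: the first-spike sweep is
  whichever sweep the caller designates.
- The deconvolution is the classical regularized spectral division — not a
  non-negative or Bayesian estimator — so the rate can ring slightly
  negative around sharp transients.
- Event detection is pulse-locked only; spontaneous-event template
  matching is out of scope.
- The CV includes failure trials and uses the sample SD; published CVs
  computed otherwise will differ by the corresponding factors.
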