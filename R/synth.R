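#' @name synthetic-data
#' @title Seeded synthetic sweep generators
#' @description
#' Every analysis stage in the package has a matching generator that produces
#' sweeps from known ground truth: passive current-step families (with
#' optional hyperpolarization-activated sag), accommodating action-potential
#' trains with exactly controllable waveform geometry, mixed GABAergic /
#' glutamatergic postsynaptic-current trains with failures, quantal
#' variability, depression and asynchronous release, and carbachol-style
#' gamma-band field potentials. Ground truth is returned alongside the sweeps
#' so parameter-recovery tests need no re-simulation. Randomness is fully
#' determined by `seed`: each sweep draws from its own substream derived from
#' `(seed, sweep index)`, so adding sweeps never perturbs earlier ones.
NULL

# Deterministic per-sweep substream: keeps sweep i reproducible regardless of
# how many sweeps are requested.
with_sweep_seed <- function(seed, i, expr) {
  sub <- (as.double(seed) * 1000003 + as.double(i) * 7919) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(sub))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

#' Generate a passive current-step family
#'
#' Simulates an RC membrane: each step of amplitude I produces a voltage
#' deflection `I * Rm * (1 - exp(-t/tau))` with `tau = Rm * Cm`, optionally
#' multiplied by a sag relaxation `(1 - g) + g * exp(-t/tau_sag)` emulating a
#' hyperpolarization-activated (Ih) conductance, plus white Gaussian noise.
#'
#' @param step_amplitudes Numeric vector of step currents (pA); one sweep per
#'   step. Repeats are allowed (e.g. 20 repeats of -20 pA for time-constant
#'   estimation).
#' @param r_m Input resistance (megaohm).
#' @param c_m Membrane capacitance (pF); `tau = r_m * c_m` microseconds.
#' @param v_rest Resting potential (mV).
#' @param step_onset,step_duration,post_duration Timing (s): pre-stimulus
#'   baseline, step length, and tail after the step.
#' @param dt Sampling interval (s); default 5e-5 (20 kHz).
#' @param noise_sd Gaussian noise SD (mV).
#' @param sag Either `NULL` (purely passive) or a list
#'   `list(g_fraction =, tau_sag_ms =)`: fraction of the steady-state
#'   deflection relaxed away by the sag conductance and its time constant.
#' @param seed Integer seed.
#' @return A list with elements `sweeps` (list of [sweep_trace()]) and
#'   `truth`: ground-truth record with `r_m`, `c_m`, `tau_ms`, `v_rest`, the
#'   sag block, and a per-step tibble (`amplitude`, noiseless `v_hyp`,
#'   `v_sag`, `sag_index`).
#' @examples
#' fam <- gen_passive_steps(c(-20, -10, 10, 20), r_m = 100, c_m = 200,
#'                          noise_sd = 0, seed = 1)
#' fam$truth$tau_ms   # 20 ms
#' @export
gen_passive_steps <- function(step_amplitudes, r_m, c_m, v_rest = -60,
                              step_onset = 0.5, step_duration = 2,
                              post_duration = 0.3, dt = 5e-5, noise_sd = 0,
                              sag = NULL, seed = 1) {
  stopifnot(r_m > 0, c_m > 0, noise_sd >= 0)
  if (!is.null(sag)) {
    stopifnot(is.list(sag), sag$g_fraction >= 0, sag$g_fraction < 1, sag$tau_sag_ms > 0)
    if (step_duration < 1) stop("`step_duration` must be >= 1 s when sag is enabled", call. = FALSE)
  }
  tau_s <- r_m * c_m * 1e-6
  total <- step_onset + step_duration + post_duration
  n <- round(total / dt)
  t <- (seq_len(n) - 1) * dt
  in_step <- t >= step_onset & t < step_onset + step_duration
  after <- t >= step_onset + step_duration
  ts <- t[in_step] - step_onset

  shape <- 1 - exp(-ts / tau_s)
  if (!is.null(sag)) {
    g <- sag$g_fraction
    shape <- shape * ((1 - g) + g * exp(-ts / (sag$tau_sag_ms * 1e-3)))
  }
  end_shape <- shape[length(shape)]

  sweeps <- vector("list", length(step_amplitudes))
  per_step <- vector("list", length(step_amplitudes))
  last200 <- ts >= step_duration - 0.2
  for (i in seq_along(step_amplitudes)) {
    amp <- step_amplitudes[[i]]
    dv_inf <- amp * r_m * 1e-3  # pA * MOhm -> microvolt; *1e-3 -> mV
    defl <- numeric(n)
    defl[in_step] <- dv_inf * shape
    defl[after] <- dv_inf * end_shape * exp(-(t[after] - (step_onset + step_duration)) / tau_s)
    v <- v_rest + defl

    extremum <- if (amp < 0) min(dv_inf * shape) else max(dv_inf * shape)
    v_hyp <- v_rest + extremum
    v_sag <- v_rest + mean(dv_inf * shape[last200])
    per_step[[i]] <- tibble::tibble(
      step = i, amplitude = amp, v_hyp = v_hyp, v_sag = v_sag,
      sag_index = (v_rest - v_sag) / (v_rest - v_hyp)
    )

    if (noise_sd > 0) {
      v <- v + with_sweep_seed(seed, i, stats::rnorm(n, 0, noise_sd))
    }
    sweeps[[i]] <- sweep_trace(
      v, dt = dt, clamp_mode = "current_clamp", holding = 0,
      stim = step_protocol(step_onset, step_duration, amplitude = amp),
      sweep_id = sprintf("step_%02d_%+gpA", i, amp)
    )
  }
  list(
    sweeps = sweeps,
    truth = list(r_m = r_m, c_m = c_m, tau_ms = tau_s * 1e3, v_rest = v_rest,
                 sag = sag, steps = dplyr::bind_rows(per_step))
  )
}

#' Sag fraction producing a target sag index
#'
#' The sag index measured on the noiseless waveform — steady-state deflection
#' (mean over the last 200 ms of the step) over peak deflection — depends only
#' on the shape parameters, not on the step current, so a 1-D root solve
#' yields the `g_fraction` for which the generated family's true index equals
#' `index`.
#'
#' @param index Target sag index in (0, 1).
#' @param tau_ms Membrane time constant (ms).
#' @param tau_sag_ms Sag relaxation time constant (ms).
#' @param step_duration Step length (s).
#' @param dt Sampling interval (s).
#' @return The `g_fraction` value to pass in the `sag` block of
#'   [gen_passive_steps()].
#' @export
sag_fraction_for_index <- function(index, tau_ms, tau_sag_ms, step_duration = 1,
                                   dt = 5e-5) {
  stopifnot(index > 0, index < 1)
  idx_of_g <- function(g) {
    ts <- seq(0, step_duration - dt, by = dt)
    shape <- (1 - exp(-ts / (tau_ms * 1e-3))) * ((1 - g) + g * exp(-ts / (tau_sag_ms * 1e-3)))
    mean(shape[ts >= step_duration - 0.2]) / max(shape)
  }
  stats::uniroot(function(g) idx_of_g(g) - index, c(1e-6, 0.95), tol = 1e-9)$root
}

#' Generate an accommodating action-potential train
#'
#' Action potentials are piecewise-analytic waveforms with exactly
#' controllable geometry, placed on a depolarized plateau: a quadratic
#' slope-ramp approach whose dV/dt crosses 10 mV/ms exactly at `threshold`; a
#' quarter-sine upstroke and cosine downstroke whose durations are solved so
#' the width at half amplitude equals `half_width`; a sine dip to
#' `threshold - ahp` followed by a half-cosine recovery to the plateau. Spike
#' onsets are placed at cumulative inter-spike intervals. Because the
#' waveform geometry is analytic, threshold / half-width / AHP recovery by
#' the analysis functions is exact up to interpolation error.
#'
#' @param isis_ms Inter-spike intervals (ms); the train has
#'   `length(isis_ms) + 1` spikes.
#' @param threshold Spike threshold (mV): voltage at the 10 mV/ms crossing.
#' @param amplitude Spike amplitude (mV): peak minus threshold.
#' @param half_width Width at half amplitude (ms).
#' @param ahp Afterhyperpolarization depth (mV): threshold minus trough.
#' @param v_rest Pre-stimulus resting potential (mV).
#' @param step_onset,duration Stimulus onset and length (s); default the
#'   800 ms train protocol.
#' @param first_spike_s First spike onset relative to the step onset (s).
#' @param step_pA Nominal injected current recorded in the stimulus metadata.
#' @param approach_offset Plateau depth below threshold (mV).
#' @param ahp_dip_ms,recovery_ms AHP dip and recovery segment durations (ms).
#' @param fall_rise_ratio Downstroke/upstroke duration ratio (dimensionless).
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise SD (mV).
#' @param seed Integer seed.
#' @return A list `sweep` (a [sweep_trace()]) and `truth`: per-spike tibble
#'   (`t_onset`, `t_peak`, `threshold`, `amplitude`, `half_width`, `ahp`,
#'   `max_rise`, `max_decay`) plus `isis_ms`, `firing_frequency` (spike count
#'   over the step duration) and `adaptation_ratio` (late-ISI mean over first
#'   ISI, same rule as [train_stats()]).
#' @export
gen_ap_train <- function(isis_ms, threshold = -41.9, amplitude = 57.4,
                         half_width = 0.74, ahp = 10.3, v_rest = -60,
                         step_onset = 0.2, duration = 0.8, first_spike_s = 0.02,
                         step_pA = NA_real_, approach_offset = 3,
                         ahp_dip_ms = 3, recovery_ms = 8, fall_rise_ratio = 2,
                         dt = 5e-5, noise_sd = 0, seed = 1) {
  stopifnot(amplitude > 0, ahp > approach_offset, half_width > 2 * dt * 1e3)
  dt_ms <- dt * 1e3

  # Geometry (all in ms). Approach: slope ramps 0 -> 12 mV/ms over D, crossing
  # 10 mV/ms at u0 = 5D/6 where the voltage has risen `approach_offset` above
  # the plateau; so D = 6*offset/25 and the ramp overshoots threshold by 11D/6.
  D <- 6 * approach_offset / 25
  over <- 11 * D / 6
  B <- amplitude - over            # sine upstroke height
  if (B <= amplitude / 2) stop("`approach_offset` too large for this amplitude", call. = FALSE)
  r <- (amplitude / 2 - over) / B  # where the rising half-amplitude crossing sits
  coef <- 1 - (2 / pi) * asin(r) + 2 * fall_rise_ratio / 3
  Tr <- half_width / coef
  Tf <- fall_rise_ratio * Tr
  Ta <- ahp_dip_ms
  Trec <- recovery_ms
  footprint <- D + Tr + Tf + Ta + Trec
  if (length(isis_ms) > 0 && footprint >= min(isis_ms)) {
    stop(sprintf("AP waveforms overlap: footprint %.2f ms >= min ISI %.2f ms",
                 footprint, min(isis_ms)), call. = FALSE)
  }

  onsets_ms <- first_spike_s * 1e3 + c(0, cumsum(isis_ms))  # relative to step onset
  if (max(onsets_ms) * 1e-3 + (Tr + Tf + Ta + Trec) * 1e-3 > duration) {
    stop("spikes do not fit inside the stimulus window", call. = FALSE)
  }

  total <- step_onset + duration + 0.1
  n <- round(total / dt)
  t <- (seq_len(n) - 1) * dt
  v0 <- threshold - approach_offset
  edge_tau <- 0.005

  v <- rep(v_rest, n)
  in_step <- t >= step_onset & t < step_onset + duration
  v[in_step] <- v_rest + (v0 - v_rest) * (1 - exp(-(t[in_step] - step_onset) / edge_tau))
  after <- t >= step_onset + duration
  v[after] <- v_rest + (v0 - v_rest) * exp(-(t[after] - (step_onset + duration)) / edge_tau)

  spike_wave <- function(u) {
    # u in ms since approach start; returns mV. Valid on [0, footprint].
    out <- numeric(length(u))
    seg1 <- u < D
    out[seg1] <- v0 + 6 * u[seg1]^2 / D
    u2 <- u - D
    seg2 <- !seg1 & u2 < Tr
    out[seg2] <- (threshold + over) + B * sin(pi / 2 * u2[seg2] / Tr)
    u3 <- u2 - Tr
    seg3 <- !seg1 & !seg2 & u3 < Tf
    out[seg3] <- threshold + amplitude * cos(pi / 2 * u3[seg3] / Tf)
    u4 <- u3 - Tf
    seg4 <- !seg1 & !seg2 & !seg3 & u4 < Ta
    out[seg4] <- threshold - ahp * sin(pi / 2 * u4[seg4] / Ta)
    u5 <- u4 - Ta
    seg5 <- !seg1 & !seg2 & !seg3 & !seg4
    trough <- threshold - ahp
    out[seg5] <- trough + (v0 - trough) * (1 - cos(pi * pmin(u5[seg5], Trec) / Trec)) / 2
    out
  }

  per_spike <- vector("list", length(onsets_ms))
  for (j in seq_along(onsets_ms)) {
    t_onset <- step_onset + onsets_ms[[j]] * 1e-3            # slope = 10 mV/ms here
    t_start <- t_onset - (5 * D / 6) * 1e-3                  # approach start
    t_end <- t_start + footprint * 1e-3
    idx <- which(t >= t_start & t < t_end)
    v[idx] <- spike_wave((t[idx] - t_start) * 1e3)
    per_spike[[j]] <- tibble::tibble(
      spike = j,
      t_onset = t_onset,
      t_peak = t_start + (D + Tr) * 1e-3,
      threshold = threshold, amplitude = amplitude,
      half_width = half_width, ahp = ahp,
      max_rise = B * pi / (2 * Tr), max_decay = -amplitude * pi / (2 * Tf)
    )
  }

  if (noise_sd > 0) v <- v + with_sweep_seed(seed, 1, stats::rnorm(n, 0, noise_sd))

  n_isi <- length(isis_ms)
  adapt <- if (n_isi >= 2) {
    k <- if (n_isi >= 5) 3 else if (n_isi >= 3) 2 else 1
    mean(utils::tail(isis_ms, k)) / isis_ms[[1]]
  } else NA_real_

  list(
    sweep = sweep_trace(v, dt = dt, clamp_mode = "current_clamp", holding = 0,
                        stim = step_protocol(step_onset, duration, amplitude = step_pA),
                        sweep_id = "ap_train"),
    truth = list(spikes = dplyr::bind_rows(per_spike), isis_ms = isis_ms,
                 firing_frequency = length(onsets_ms) / duration,
                 adaptation_ratio = adapt)
  )
}

# Unit-peak bi-exponential conductance waveform.
biexp_unit <- function(t_s, tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms * 1e-3
  td <- tau_decay_ms * 1e-3
  stopifnot(tr < td)
  t_pk <- (td * tr / (td - tr)) * log(td / tr)
  norm <- exp(-t_pk / td) - exp(-t_pk / tr)
  out <- (exp(-t_s / td) - exp(-t_s / tr)) / norm
  out[t_s < 0] <- 0
  out
}

#' Generate voltage-clamp synaptic train sweeps
#'
#' Each presynaptic pulse can release a GABAergic and/or a glutamatergic
#' quantum. Per pulse and component: a Bernoulli success/failure draw, a
#' lognormal quantal scale with coefficient of variation `cv_q` (mean 1),
#' multiplicative short-term depression (amplitude scaled by
#' `depression_f` per preceding success of that component), and a release
#' time — synchronous (fixed latency plus Gaussian jitter) or, with per-pulse
#' probability `async_fraction[i]`, asynchronous, uniform in the
#' `async_window_ms` before the next pulse. The recorded current is
#' `sum_i g_i(t) * (v_hold - e_i)` with unit-peak bi-exponential conductance
#' waveforms, so a GABA event at a holding potential above its reversal is
#' outward (positive) while an AMPA event at the same holding potential is
#' inward (negative) — the polarity dissociation the analysis exploits.
#'
#' @param pulse_times Presynaptic pulse onset times (s), strictly increasing.
#' @param n_sweeps Number of trial sweeps.
#' @param g_gaba,g_ampa Peak conductances per quantum (nS); 0 disables the
#'   component.
#' @param tau_rise_gaba,tau_decay_gaba,tau_rise_ampa,tau_decay_ampa
#'   Bi-exponential kinetics (ms).
#' @param e_gaba,e_ampa Reversal potentials (mV).
#' @param v_hold Holding potential (mV).
#' @param failure_p Per-pulse release failure probability in `[0, 1)`.
#' @param cv_q Quantal amplitude coefficient of variation (lognormal).
#' @param depression_f Multiplicative depression factor per preceding success.
#' @param latency_ms,jitter_ms Synchronous release latency and Gaussian jitter
#'   SD (ms).
#' @param async_fraction Per-pulse probability of asynchronous release, length
#'   1 or `length(pulse_times)`; default 0.
#' @param async_window_ms Asynchronous release window before the next pulse
#'   (ms); must not exceed the inter-pulse interval.
#' @param duration Sweep length (s); default extends 150 ms past the last
#'   pulse.
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian current noise SD (pA).
#' @param seed Integer seed.
#' @return A list `sweeps` (list of voltage-clamp [sweep_trace()]) and
#'   `truth`: a tibble with one row per pulse, component and sweep
#'   (`sweep`, `pulse`, `component`, `is_failure`, `is_async`,
#'   `release_time`, `conductance` in nS, `peak_pA`).
#' @export
gen_synaptic_trace <- function(pulse_times, n_sweeps = 1,
                               g_gaba = 1, g_ampa = 0,
                               tau_rise_gaba = 0.5, tau_decay_gaba = 10,
                               tau_rise_ampa = 0.2, tau_decay_ampa = 2,
                               e_gaba = -60, e_ampa = 0, v_hold = -40,
                               failure_p = 0, cv_q = 0, depression_f = 1,
                               latency_ms = 1, jitter_ms = 0.2,
                               async_fraction = 0, async_window_ms = 15,
                               duration = NULL, dt = 5e-5, noise_sd = 0,
                               seed = 1) {
  pulse_times <- as.numeric(pulse_times)
  stopifnot(length(pulse_times) >= 1, failure_p >= 0, failure_p < 1,
            cv_q >= 0, depression_f > 0, noise_sd >= 0)
  if (length(pulse_times) > 1L) {
    ipi <- diff(pulse_times)
    if (any(ipi <= 0)) stop("`pulse_times` must be strictly increasing", call. = FALSE)
    if (async_window_ms * 1e-3 > min(ipi) + 1e-12) {
      stop("`async_window_ms` exceeds the inter-pulse interval", call. = FALSE)
    }
    period <- stats::median(ipi)
  } else {
    period <- 0.02
  }
  np <- length(pulse_times)
  async_fraction <- rep_len(async_fraction, np)
  comps <- list(
    GABA = list(g = g_gaba, tr = tau_rise_gaba, td = tau_decay_gaba, e = e_gaba),
    Glu  = list(g = g_ampa, tr = tau_rise_ampa, td = tau_decay_ampa, e = e_ampa)
  )
  for (nm in names(comps)) {
    cc <- comps[[nm]]
    if (cc$g > 0 && abs(v_hold - cc$e) < 1e-9) {
      stop(sprintf("%s reversal equals the holding potential: zero driving force", nm), call. = FALSE)
    }
  }
  if (is.null(duration)) duration <- max(pulse_times) + 0.15
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  virtual_next <- c(pulse_times[-1], pulse_times[np] + period)

  sweeps <- vector("list", n_sweeps)
  truth <- vector("list", n_sweeps)
  sdlog <- sqrt(log(1 + cv_q^2))

  for (s in seq_len(n_sweeps)) {
    rows <- with_sweep_seed(seed, s, {
      out <- list()
      for (nm in names(comps)) {
        cc <- comps[[nm]]
        if (cc$g <= 0) next
        n_succ <- 0
        for (i in seq_len(np)) {
          fail <- stats::runif(1) < failure_p
          q <- if (cv_q > 0) stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
          dep <- depression_f^n_succ
          is_async <- stats::runif(1) < async_fraction[[i]]
          rel <- if (is_async) {
            stats::runif(1, virtual_next[[i]] - async_window_ms * 1e-3, virtual_next[[i]])
          } else {
            pulse_times[[i]] + (latency_ms + stats::rnorm(1, 0, jitter_ms)) * 1e-3
          }
          g_amp <- if (fail) 0 else cc$g * q * dep
          if (!fail) n_succ <- n_succ + 1
          out[[length(out) + 1L]] <- tibble::tibble(
            sweep = s, pulse = i, component = nm, is_failure = fail,
            is_async = is_async, release_time = rel, conductance = g_amp,
            peak_pA = g_amp * (v_hold - cc$e)
          )
        }
      }
      dplyr::bind_rows(out)
    })

    i_trace <- numeric(n)
    if (nrow(rows) > 0) {
      for (k in seq_len(nrow(rows))) {
        if (rows$conductance[[k]] == 0) next
        cc <- comps[[rows$component[[k]]]]
        i0 <- floor(rows$release_time[[k]] / dt) + 1L
        span <- min(n, i0 + ceiling(8 * cc$td * 1e-3 / dt))
        if (i0 > n) next
        idx <- i0:span
        i_trace[idx] <- i_trace[idx] +
          rows$conductance[[k]] * (v_hold - cc$e) *
          biexp_unit(t[idx] - rows$release_time[[k]], cc$tr, cc$td)
      }
    }
    if (noise_sd > 0) {
      i_trace <- i_trace + with_sweep_seed(seed, s + 10^6, stats::rnorm(n, 0, noise_sd))
    }
    sweeps[[s]] <- sweep_trace(
      i_trace, dt = dt, clamp_mode = "voltage_clamp", holding = v_hold,
      stim = step_protocol(pulse_times[[1]], max(pulse_times) - pulse_times[[1]],
                           pulse_times = pulse_times,
                           pulse_rate = if (np > 1) 1 / period else NA_real_),
      sweep_id = sprintf("trial_%03d", s)
    )
    truth[[s]] <- rows
  }
  list(sweeps = sweeps, truth = dplyr::bind_rows(truth))
}

#' Generate a gamma-band local field potential epoch
#'
#' A sinusoid at `f0` plus white broadband noise, emulating a
#' carbachol-induced gamma oscillation recorded in stratum pyramidale.
#'
#' @param f0 Oscillation frequency (Hz), below Nyquist.
#' @param amp Sinusoid amplitude (mV).
#' @param duration Epoch length (s); epochs shorter than the conventional
#'   10 s raise a warning.
#' @param broadband_sd White-noise SD (mV).
#' @param dt Sampling interval (s); 5e-4 (2 kHz) is ample for the 20-80 Hz
#'   band.
#' @param seed Integer seed.
#' @return A field-mode [sweep_trace()].
#' @export
gen_lfp <- function(f0 = 40, amp = 0.1, duration = 10, broadband_sd = 0.02,
                    dt = 5e-4, seed = 1) {
  stopifnot(f0 > 0, f0 < 0.5 / dt, amp >= 0, broadband_sd >= 0)
  if (duration < 10) warning("LFP epoch shorter than the conventional 10 s", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  x <- amp * sin(2 * pi * f0 * t)
  if (broadband_sd > 0) x <- x + with_sweep_seed(seed, 1, stats::rnorm(n, 0, broadband_sd))
  sweep_trace(x, dt = dt, clamp_mode = "field", holding = NA_real_, sweep_id = "lfp")
}
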