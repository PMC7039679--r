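#' @name synaptic-analysis
#' @title Unitary synaptic event quantification
#' @description
#' Per-trial postsynaptic-current measurement against presynaptic pulse
#' times, summary statistics of unitary transmission (amplitude including
#' failures, potency excluding them, failure rate, paired-pulse ratio,
#' coefficient of variation, latency, kinetics), conversion of peak currents
#' to conductances via driving force, polarity-based dissociation of
#' GABAergic (outward at holding potentials above E_Cl) and glutamatergic
#' (inward below 0 mV) components, depolarization-induced suppression of
#' inhibition (DSI), and Nernst reversal potentials from pipette / bath
#' solution compositions.
NULL

# Ion stoichiometry of the salts used in common pipette and bath solutions.
.salt_ions <- list(
  "KCl" = c(K = 1, Cl = 1),
  "NaCl" = c(Na = 1, Cl = 1),
  "CsCl" = c(Cs = 1, Cl = 1),
  "MgCl2" = c(Mg = 1, Cl = 2),
  "CaCl2" = c(Ca = 1, Cl = 2),
  "K-gluconate" = c(K = 1, gluconate = 1),
  "Cs-methanesulfonate" = c(Cs = 1, methanesulfonate = 1),
  "NaHCO3" = c(Na = 1, HCO3 = 1),
  "NaH2PO4" = c(Na = 1, H2PO4 = 1),
  "Na2ATP" = c(Na = 2),
  "NaGTP" = c(Na = 1),
  "HEPES" = c(),
  "EGTA" = c(),
  "BAPTA" = c(),
  "QX-314" = c(),
  "glucose" = c()
)

#' Total concentration of an ion in a solution
#'
#' Sums the ion's contribution across all salts of a named
#' salt-concentration vector (mM), using a built-in stoichiometry table
#' (e.g. `MgCl2` contributes two chloride per formula unit). A component
#' named exactly like the ion is taken as the free ion itself.
#'
#' @param solution Named numeric vector of salt concentrations (mM).
#' @param ion Ion name, e.g. `"Cl"`, `"K"`, `"Na"`.
#' @return Total ion concentration (mM).
#' @examples
#' ion_concentration(c(KCl = 5, MgCl2 = 3), "Cl")  # 11
#' @export
ion_concentration <- function(solution, ion) {
  stopifnot(is.numeric(solution), !is.null(names(solution)))
  total <- 0
  for (salt in names(solution)) {
    if (salt == ion) {
      total <- total + solution[[salt]]
    } else if (salt %in% names(.salt_ions)) {
      cnt <- .salt_ions[[salt]]
      if (ion %in% names(cnt)) total <- total + solution[[salt]] * cnt[[ion]]
    }
  }
  total
}

#' Standard solution recipes
#'
#' Built-in pipette and bath compositions (mM) for convenience: a
#' potassium-gluconate current-clamp internal, a high-chloride CsCl
#' voltage-clamp internal, and the recording artificial cerebrospinal fluid.
#'
#' @return Named numeric vector of salt concentrations (mM).
#' @export
solution_kgluconate_internal <- function() {
  c("K-gluconate" = 130, "KCl" = 5, "HEPES" = 10, "MgCl2" = 3,
    "Na2ATP" = 2, "NaGTP" = 0.3, "EGTA" = 0.6)
}

#' @rdname solution_kgluconate_internal
#' @export
solution_cscl_internal <- function() {
  c("CsCl" = 130, "NaCl" = 5, "HEPES" = 10, "MgCl2" = 3,
    "Na2ATP" = 2, "NaGTP" = 0.3, "EGTA" = 0.6, "QX-314" = 2)
}

#' @rdname solution_kgluconate_internal
#' @export
solution_acsf <- function() {
  c("NaCl" = 130, "KCl" = 3.5, "NaHCO3" = 24, "NaH2PO4" = 1.25,
    "MgCl2" = 1.5, "CaCl2" = 2.5, "glucose" = 10)
}

#' Nernst equilibrium potential
#'
#' `E = (R T / z F) ln([out]/[in])` in millivolts, with the ion's total
#' concentration summed across all salts on each side via
#' [ion_concentration()].
#'
#' @param internal,external Named salt-concentration vectors (mM).
#' @param ion Ion species name.
#' @param z Ion valence (e.g. -1 for chloride).
#' @param temperature Temperature in degrees Celsius.
#' @return Equilibrium potential (mV).
#' @examples
#' nernst(solution_kgluconate_internal(), solution_acsf(),
#'        ion = "Cl", z = -1, temperature = 33)  # about -67 mV
#' @export
nernst <- function(internal, external, ion = "Cl", z = -1, temperature = 33) {
  cin <- ion_concentration(internal, ion)
  cout <- ion_concentration(external, ion)
  if (cin <= 0 || cout <= 0) {
    stop(sprintf("'%s' concentration must be positive on both sides (in %.3g, out %.3g mM)",
                 ion, cin, cout), call. = FALSE)
  }
  R <- 8.31446
  FARADAY <- 96485.332
  T_k <- temperature + 273.15
  1e3 * (R * T_k / (z * FARADAY)) * log(cout / cin)
}

#' Measure pulse-locked postsynaptic events
#'
#' For each presynaptic pulse the baseline-subtracted extremum within
#' `(pulse, pulse + window_ms]` is taken as the event peak (baseline: mean of
#' the `baseline_ms` preceding the pulse). Trials whose peak does not exceed
#' `failure_k` times the baseline noise SD (estimated from the pre-first-pulse
#' segment) are flagged as transmission failures and their amplitude is
#' recorded as 0, so that amplitude averages include failures by
#' construction. Latency is pulse time to the first crossing of 10% of the
#' peak, interpolated between samples; the onset polarity is the sign of the
#' event at onset (outward positive).
#'
#' Peaks are picked on a lightly smoothed copy of the trace
#' (`smooth_reps` binomial passes, default 20, a Gaussian blur of roughly
#' 0.16 ms at 20 kHz): the extremum of a raw white-noise trace over a
#' multi-millisecond window is biased upward by extreme-value statistics,
#' which would both inflate amplitudes and defeat the noise-SD failure
#' criterion. The baseline noise SD is estimated on the same smoothed trace
#' so the criterion stays calibrated.
#'
#' @param sweeps One voltage-clamp [sweep_trace()] or a list of trial sweeps.
#' @param pulse_times Presynaptic pulse times (s); defaults to the sweep's
#'   stimulus metadata.
#' @param window_ms Response window after each pulse (ms); must not exceed
#'   the inter-pulse interval.
#' @param baseline_ms Pre-pulse baseline window (ms).
#' @param polarity `"auto"` (largest absolute deviation), `"inward"`, or
#'   `"outward"`.
#' @param failure_k Failure criterion in baseline-noise SDs (default 3).
#' @param smooth_reps Binomial smoothing passes applied before measurement.
#' @return Tibble with one row per trial and pulse: `trial`, `pulse`,
#'   `amplitude` (pA, signed; 0 for failures), `is_failure`, `latency_ms`,
#'   `polarity`.
#' @export
measure_events <- function(sweeps, pulse_times = NULL, window_ms = 15,
                           baseline_ms = 5,
                           polarity = c("auto", "inward", "outward"),
                           failure_k = 3, smooth_reps = 20) {
  polarity <- match.arg(polarity)
  if (inherits(sweeps, "pk_sweep")) sweeps <- list(sweeps)
  purrr::imap_dfr(sweeps, function(sw, trial) {
    pt <- pulse_times
    if (is.null(pt)) {
      if (is.null(sw$stim) || is.null(sw$stim$pulse_times)) {
        stop("no `pulse_times` given and the sweep carries no train metadata", call. = FALSE)
      }
      pt <- sw$stim$pulse_times
    }
    if (length(pt) > 1 && window_ms * 1e-3 > min(diff(pt)) + 1e-12) {
      stop("response window overlaps the next pulse", call. = FALSE)
    }
    t <- sweep_times(sw)
    x <- binomial_smooth(sw$samples, smooth_reps)
    noise_sd <- stats::sd(x[t < pt[[1]]])
    if (!is.finite(noise_sd)) noise_sd <- 0

    purrr::map_dfr(seq_along(pt), function(i) {
      p <- pt[[i]]
      base <- mean(x[t >= p - baseline_ms * 1e-3 & t < p])
      win <- which(t > p & t <= p + window_ms * 1e-3)
      dev <- x[win] - base
      peak <- switch(polarity,
                     auto = dev[[which.max(abs(dev))]],
                     inward = min(dev),
                     outward = max(dev))
      fail <- abs(peak) <= failure_k * noise_sd
      lat <- NA_real_
      pol <- NA_character_
      if (!fail) {
        thresh <- 0.1 * peak
        hit <- if (peak > 0) which(dev >= thresh) else which(dev <= thresh)
        if (length(hit) > 0) {
          k <- hit[[1]]
          if (k > 1) {
            frac <- (thresh - dev[[k - 1]]) / (dev[[k]] - dev[[k - 1]])
            lat <- (t[win[[k - 1]]] + frac * sw$dt - p) * 1e3
          } else {
            lat <- (t[win[[k]]] - p) * 1e3
          }
        }
        pol <- if (peak > 0) "outward" else "inward"
      }
      tibble::tibble(trial = trial, pulse = i,
                     amplitude = if (fail) 0 else peak,
                     is_failure = fail, latency_ms = lat, polarity = pol)
    })
  })
}

#' Unitary transmission summary statistics
#'
#' Amplitude is the mean first-pulse peak over all trials including failures
#' (recorded as 0); potency is the mean over successes only, so
#' `amplitude = potency * (1 - failure_rate)` holds by construction. The
#' coefficient of variation is the sample (n-1) SD over mean of the
#' first-pulse amplitudes, failures included. The paired-pulse ratio is the
#' mean second-pulse amplitude divided by the mean first-pulse amplitude.
#'
#' @param events Tibble from [measure_events()] over >= 10 trials.
#' @param first_pulse,second_pulse Pulse indices used for the statistics.
#' @return One-row tibble: `n_trials`, `amplitude`, `potency` (pA),
#'   `failure_rate`, `cv`, `ppr`, `latency_mean`, `latency_sd` (ms).
#' @export
unitary_stats <- function(events, first_pulse = 1, second_pulse = 2) {
  e1 <- dplyr::filter(events, .data$pulse == first_pulse)
  n <- nrow(e1)
  if (n < 10) stop("need >= 10 trials for unitary statistics", call. = FALSE)
  amp <- mean(e1$amplitude)
  fr <- mean(e1$is_failure)
  pot <- if (all(e1$is_failure)) NA_real_ else mean(e1$amplitude[!e1$is_failure])
  cv <- if (all(e1$is_failure)) {
    NA_real_
  } else if (amp == 0) {
    stop("mean amplitude is zero: CV undefined", call. = FALSE)
  } else {
    stats::sd(e1$amplitude) / amp
  }
  e2 <- dplyr::filter(events, .data$pulse == second_pulse)
  ppr <- if (nrow(e2) > 0 && amp != 0) mean(e2$amplitude) / amp else NA_real_
  lat <- e1$latency_ms[!e1$is_failure]
  tibble::tibble(n_trials = n, amplitude = amp, potency = pot,
                 failure_rate = fr, cv = cv, ppr = ppr,
                 latency_mean = if (length(lat)) mean(lat) else NA_real_,
                 latency_sd = if (length(lat) > 1) stats::sd(lat) else NA_real_)
}

#' Rise time and decay time constant of an averaged event
#'
#' Rise time is the 20-80% interval on the rising phase (interpolated);
#' the decay time constant comes from a single-exponential least-squares fit
#' of the segment from the peak back to baseline. Both are invariant to
#' amplitude scaling. The trace should be an average of at least 5 aligned
#' events with the pre-event baseline at zero (or supply `baseline`).
#'
#' @param sweep Voltage-clamp [sweep_trace()] holding the averaged event.
#' @param baseline Baseline current level (pA) subtracted before analysis.
#' @return One-row tibble: `rise_time_ms`, `decay_tau_ms`, `peak_pA`.
#' @export
event_kinetics <- function(sweep, baseline = 0) {
  stopifnot(inherits(sweep, "pk_sweep"))
  x <- sweep$samples - baseline
  t <- sweep_times(sweep)
  i_pk <- which.max(abs(x))
  peak <- x[[i_pk]]
  s <- sign(peak)
  y <- x * s  # work on positive-deflection copy

  lvl <- function(frac) {
    target <- frac * y[[i_pk]]
    seg <- y[seq_len(i_pk)]
    k <- which(seg[-length(seg)] < target & seg[-1] >= target)
    if (length(k) == 0) return(t[[1]])
    k <- k[[length(k)]]
    t[[k]] + sweep$dt * (target - seg[[k]]) / (seg[[k + 1]] - seg[[k]])
  }
  rise <- (lvl(0.8) - lvl(0.2)) * 1e3

  df <- data.frame(ts = (t[i_pk:length(t)] - t[[i_pk]]) * 1e3, yy = y[i_pk:length(y)])
  below <- which(df$yy < df$yy[[1]] / exp(1))
  tau0 <- if (length(below)) df$ts[[below[[1]]]] else max(df$ts) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-ts / tau), data = df,
                      start = list(A = df$yy[[1]], tau = max(tau0, sweep$dt * 1e3))),
    error = function(e) {
      stop(sprintf("decay fit did not converge (%s); residual trace range [%.3g, %.3g] pA",
                   conditionMessage(e), min(df$yy), max(df$yy)), call. = FALSE)
    }
  )
  tibble::tibble(rise_time_ms = rise,
                 decay_tau_ms = unname(stats::coef(fit)[["tau"]]),
                 peak_pA = peak)
}

#' Convert a peak current to a conductance
#'
#' `G = I_peak / (V_hold - E_rev)` with pA over mV giving nS. The sign of the
#' measured current must match the driving force (an inward current with an
#' outward driving force indicates a mis-assigned component and raises an
#' error); the returned conductance is non-negative.
#'
#' @param peak Peak current (pA, signed; inward negative).
#' @param v_hold Holding potential (mV).
#' @param e_rev Reversal potential of the component (mV).
#' @return Conductance (nS).
#' @examples
#' to_conductance(200, v_hold = -40, e_rev = -60)   # 10 nS (outward GABA)
#' to_conductance(-100, v_hold = -30, e_rev = 0)    # 3.33 nS (inward Glu)
#' @export
to_conductance <- function(peak, v_hold, e_rev) {
  drive <- v_hold - e_rev
  if (abs(drive) < 5) {
    stop("driving force below 5 mV: conductance conversion unreliable", call. = FALSE)
  }
  if (peak == 0) return(0)
  if (sign(peak) != sign(drive)) {
    stop(sprintf("current sign (%+g pA) inconsistent with driving force (%+g mV): component mis-assigned?",
                 peak, drive), call. = FALSE)
  }
  peak / drive
}

#' Dissociate GABAergic and glutamatergic components by polarity
#'
#' At a holding potential between the chloride and glutamate reversals,
#' GABA_A-receptor currents are outward and AMPA-receptor currents inward,
#' so the two components of a mixed response separate unambiguously by sign:
#' the outward peak is converted to a GABA conductance against `e_gaba` and
#' the inward peak to a glutamate conductance against `e_glu`. Peaks below
#' `failure_k` baseline-noise SDs count as absent (conductance 0). The ratio
#' `G_GABA / G_Glu` is `Inf` for a pure GABA response and `NA` when both
#' components are absent.
#'
#' @param sweeps One averaged sweep or list of trial sweeps (voltage clamp).
#' @param pulse_times Stimulus times (s); defaults to sweep metadata.
#' @param v_hold Holding potential (mV); defaults to the sweep's `holding`.
#' @param e_gaba,e_glu Reversal potentials (mV). `e_gaba + 5 <= v_hold <=
#'   e_glu - 5` is required so both driving forces are usable.
#' @param window_ms,baseline_ms,failure_k As in [measure_events()].
#' @return List with `components` (tibble: `component`, `peak_pA`, `g_nS`,
#'   `e_rev`, `v_hold`) and `ratio` (G_GABA / G_Glu).
#' @export
split_components <- function(sweeps, pulse_times = NULL, v_hold = NULL,
                             e_gaba = -60, e_glu = 0, window_ms = 15,
                             baseline_ms = 5, failure_k = 3) {
  if (inherits(sweeps, "pk_sweep")) sweeps <- list(sweeps)
  if (is.null(v_hold)) v_hold <- sweeps[[1]]$holding
  if (!(v_hold >= e_gaba + 5 && v_hold <= e_glu - 5)) {
    stop(sprintf("holding %g mV must lie in [E_GABA + 5, E_Glu - 5] = [%g, %g] mV for polarity dissociation",
                 v_hold, e_gaba + 5, e_glu - 5), call. = FALSE)
  }
  out_ev <- measure_events(sweeps, pulse_times = pulse_times, window_ms = window_ms,
                           baseline_ms = baseline_ms, polarity = "outward",
                           failure_k = failure_k)
  in_ev <- measure_events(sweeps, pulse_times = pulse_times, window_ms = window_ms,
                          baseline_ms = baseline_ms, polarity = "inward",
                          failure_k = failure_k)
  pk_out <- mean(out_ev$amplitude)
  pk_in <- mean(in_ev$amplitude)
  g_gaba <- if (pk_out > 0) to_conductance(pk_out, v_hold, e_gaba) else 0
  g_glu <- if (pk_in < 0) to_conductance(pk_in, v_hold, e_glu) else 0
  ratio <- if (g_gaba == 0 && g_glu == 0) NA_real_ else g_gaba / g_glu
  list(
    components = tibble::tibble(
      component = c("GABA", "Glu"), peak_pA = c(pk_out, pk_in),
      g_nS = c(g_gaba, g_glu), e_rev = c(e_gaba, e_glu), v_hold = v_hold),
    ratio = ratio
  )
}

#' Depolarization-induced suppression of inhibition
#'
#' Averages event amplitudes per condition (control, post-depolarization
#' DSI test, recovery; at least 5 events each) and quantifies suppression as
#' `100 * (1 - dsi / ctl)` percent.
#'
#' @param ctl_amplitudes,dsi_amplitudes,recovery_amplitudes Numeric vectors
#'   of per-event peak amplitudes (pA); recovery may be `NULL`.
#' @return One-row tibble: `ctl_amplitude`, `dsi_amplitude`,
#'   `recovery_amplitude` (pA), `suppression_pct`.
#' @examples
#' dsi(rep(-200, 6), rep(-50, 6))  # 75% suppression
#' @export
dsi <- function(ctl_amplitudes, dsi_amplitudes, recovery_amplitudes = NULL) {
  stopifnot(length(ctl_amplitudes) >= 5, length(dsi_amplitudes) >= 5)
  ctl <- mean(ctl_amplitudes)
  if (ctl == 0) stop("control amplitude is zero: suppression undefined", call. = FALSE)
  dsi_m <- mean(dsi_amplitudes)
  rec <- if (is.null(recovery_amplitudes)) NA_real_ else {
    stopifnot(length(recovery_amplitudes) >= 5)
    mean(recovery_amplitudes)
  }
  tibble::tibble(ctl_amplitude = ctl, dsi_amplitude = dsi_m,
                 recovery_amplitude = rec,
                 suppression_pct = 100 * (1 - dsi_m / ctl))
}
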