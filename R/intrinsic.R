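#' Resting membrane potential from the pre-stimulus baseline
#'
#' Mean of the baseline samples. If the sweep carries stimulus metadata at
#' least 100 ms of pre-stimulus baseline is required; a sweep without any
#' stimulus is treated as all baseline.
#'
#' @param sweep A current-clamp [sweep_trace()].
#' @return Resting potential (mV).
#' @export
resting_potential <- function(sweep) {
  stopifnot(inherits(sweep, "pk_sweep"), sweep$clamp_mode == "current_clamp")
  if (is.null(sweep$stim)) return(mean(sweep$samples))
  if (sweep$stim$onset < 0.1) {
    stop("need >= 100 ms of pre-stimulus baseline to estimate the resting potential", call. = FALSE)
  }
  t <- sweep_times(sweep)
  mean(sweep$samples[t < sweep$stim$onset])
}

step_deflections <- function(sweeps, ss_window = 0.2) {
  purrr::map_dfr(sweeps, function(sw) {
    stopifnot(inherits(sw, "pk_sweep"))
    if (is.null(sw$stim)) stop("every sweep needs stimulus metadata", call. = FALSE)
    t <- sweep_times(sw)
    on <- sw$stim$onset
    off <- on + sw$stim$duration
    base <- mean(sw$samples[t < on])
    ss <- mean(sw$samples[t >= off - ss_window & t < off])
    tibble::tibble(sweep_id = sw$sweep_id, amplitude = sw$stim$amplitude,
                   baseline = base, v_ss = ss, deflection = ss - base)
  })
}

#' Input resistance from a current-step family
#'
#' Ordinary least-squares slope of steady-state voltage deflection (mean over
#' the last 200 ms of each step, relative to the pre-step baseline) against
#' injected current. Steps deflecting the membrane by more than
#' `max_deflection` (default 15 mV, the linear range around rest) are
#' excluded before fitting.
#'
#' @param sweeps List of current-clamp [sweep_trace()] objects, each with step
#'   metadata; or the `sweeps` element of [gen_passive_steps()].
#' @param max_deflection Exclusion bound on |deflection| (mV).
#' @param ss_window Steady-state averaging window at the end of the step (s).
#' @return An object of class `pk_rm_fit`: list with `r_m` (megaohm), the
#'   per-step tibble `steps` (with `included` flag) and the underlying `lm`
#'   fit. `tidy()` returns the per-step table, `glance()` the one-row summary.
#' @export
input_resistance <- function(sweeps, max_deflection = 15, ss_window = 0.2) {
  steps <- step_deflections(sweeps, ss_window = ss_window)
  steps$included <- abs(steps$deflection) <= max_deflection
  used <- steps[steps$included, ]
  if (nrow(used) < 3) {
    stop(sprintf("need >= 3 steps within +/-%g mV of rest; excluded: %s",
                 max_deflection,
                 paste(steps$sweep_id[!steps$included], collapse = ", ")),
         call. = FALSE)
  }
  fit <- stats::lm(deflection ~ amplitude, data = used)
  structure(list(r_m = unname(stats::coef(fit)[["amplitude"]]) * 1e3,
                 steps = steps, fit = fit),
            class = "pk_rm_fit")
}

#' @export
print.pk_rm_fit <- function(x, ...) {
  cat(sprintf("Input resistance: %.1f MOhm (%d/%d steps within the linear range)\n",
              x$r_m, sum(x$steps$included), nrow(x$steps)))
  invisible(x)
}

#' Membrane time constant from averaged hyperpolarizing pulses
#'
#' Averages repeated identical pulses (conventionally 20 repeats of -20 pA,
#' 400 ms), then least-squares fits a single exponential
#' `V(t) = V0 + dV * (1 - exp(-t / tau))` over the window from pulse onset to
#' five times the initial tau guess. If `r_m` is supplied the membrane
#' capacitance `c_m = tau / r_m` is also returned (in pF when tau is ms and
#' r_m megaohm).
#'
#' @param sweeps List of current-clamp [sweep_trace()] repeats with identical
#'   pulse timing.
#' @param r_m Optional input resistance (megaohm) for the capacitance.
#' @param tau_guess_ms Initial guess for tau (ms); also sets the fit window.
#' @return An object of class `pk_tau_fit`: list with `tau_ms`, `c_m` (pF or
#'   `NA`), `fit` (the `nls` object) and the averaged trace window.
#' @export
time_constant <- function(sweeps, r_m = NULL, tau_guess_ms = 20) {
  stopifnot(length(sweeps) >= 1)
  stims <- lapply(sweeps, function(s) s$stim)
  if (any(vapply(stims, is.null, logical(1)))) {
    stop("every sweep needs stimulus metadata", call. = FALSE)
  }
  onsets <- vapply(stims, function(s) s$onset, numeric(1))
  if (stats::sd(c(onsets, onsets[1])) > 0) stop("pulse timing differs across repeats", call. = FALSE)
  dt <- sweeps[[1]]$dt
  nmin <- min(vapply(sweeps, function(s) length(s$samples), integer(1)))
  avg <- rowMeans(vapply(sweeps, function(s) s$samples[seq_len(nmin)], numeric(nmin)))
  t <- (seq_len(nmin) - 1) * dt

  on <- onsets[[1]]
  win <- t >= on & t <= on + 5 * tau_guess_ms * 1e-3
  df <- data.frame(ts = t[win] - on, y = avg[win])
  v0 <- df$y[[1]]
  dv <- mean(utils::tail(df$y, max(5, round(nrow(df) / 20)))) - v0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ V0 + dV * (1 - exp(-ts / tau)),
                      data = df,
                      start = list(V0 = v0, dV = dv, tau = tau_guess_ms * 1e-3)),
    error = function(e) stop("single-exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  tau_ms <- unname(stats::coef(fit)[["tau"]]) * 1e3
  if (tau_ms <= 0.5 || tau_ms >= 200) {
    stop(sprintf("fitted tau %.3g ms outside the physiological range (0.5, 200) ms", tau_ms),
         call. = FALSE)
  }
  c_m <- if (!is.null(r_m)) tau_ms / r_m * 1e3 else NA_real_
  structure(list(tau_ms = tau_ms, c_m = c_m, fit = fit, n_repeats = length(sweeps)),
            class = "pk_tau_fit")
}

#' @export
print.pk_tau_fit <- function(x, ...) {
  cat(sprintf("Membrane time constant: %.2f ms (%d repeats averaged)", x$tau_ms, x$n_repeats))
  if (!is.na(x$c_m)) cat(sprintf("; Cm = %.1f pF", x$c_m))
  cat("\n")
  invisible(x)
}

#' Sag index at the current giving Vsag = -80 mV
#'
#' For each hyperpolarizing step the peak deflection `V_hyp` (mean over a
#' short window centred on the trace minimum, to avoid the downward
#' extreme-value bias a single noisy sample would carry) and the steady-state
#' level `V_sag` (mean over the last 200 ms of the step) are measured. Both
#' are fit against injected current with cubic polynomials (quadratic when
#' fewer than 5 steps are available), the current `I*` with
#' `V_sag(I*) = -80 mV` is solved within the sampled range (no
#' extrapolation), and the index `(v_rest - V_sag(I*)) / (v_rest - V_hyp(I*))`
#' is returned. An index of 1 means no sag; smaller values mean stronger
#' Ih-mediated rebound.
#'
#' @param sweeps Hyperpolarizing current-clamp step family (>= 4 steps
#'   bracketing -80 mV).
#' @param v_rest Resting potential (mV).
#' @param target_v_sag Target steady-state voltage (mV), default -80.
#' @param ss_window Steady-state window (s).
#' @param hyp_window_ms Averaging window around the minimum for `V_hyp` (ms).
#' @return An object of class `pk_sag_fit`: list with `sag_index`, `i_star`
#'   (pA), `v_hyp`, `v_sag` at `I*`, and the per-step tibble.
#' @export
sag_index <- function(sweeps, v_rest, target_v_sag = -80, ss_window = 0.2,
                      hyp_window_ms = 5) {
  hyp <- Filter(function(s) !is.null(s$stim) && s$stim$amplitude < 0, sweeps)
  if (length(hyp) < 4) stop("need >= 4 hyperpolarizing steps", call. = FALSE)

  per <- purrr::map_dfr(hyp, function(sw) {
    t <- sweep_times(sw)
    on <- sw$stim$onset
    off <- on + sw$stim$duration
    idx <- which(t >= on & t < off)
    v <- sw$samples[idx]
    k <- which.min(v)
    half_w <- max(1L, round(hyp_window_ms * 1e-3 / sw$dt / 2))
    lo <- max(1L, k - half_w)
    hi <- min(length(v), k + half_w)
    tibble::tibble(amplitude = sw$stim$amplitude,
                   v_hyp = mean(v[lo:hi]),
                   v_sag = mean(v[t[idx] >= off - ss_window]))
  })

  if (target_v_sag < min(per$v_sag) || target_v_sag > max(per$v_sag)) {
    stop(sprintf("target V_sag %g mV outside the sampled range [%.1f, %.1f]; refusing to extrapolate",
                 target_v_sag, min(per$v_sag), max(per$v_sag)), call. = FALSE)
  }
  deg <- if (nrow(per) >= 5) 3 else 2
  fit_sag <- stats::lm(v_sag ~ poly(amplitude, deg, raw = TRUE), data = per)
  fit_hyp <- stats::lm(v_hyp ~ poly(amplitude, deg, raw = TRUE), data = per)
  pred <- function(fit, i) unname(stats::predict(fit, newdata = data.frame(amplitude = i)))

  i_star <- stats::uniroot(function(i) pred(fit_sag, i) - target_v_sag,
                           range(per$amplitude), tol = 1e-9, extendInt = "no")$root
  v_sag_star <- pred(fit_sag, i_star)
  v_hyp_star <- pred(fit_hyp, i_star)
  structure(list(sag_index = (v_rest - v_sag_star) / (v_rest - v_hyp_star),
                 i_star = i_star, v_hyp = v_hyp_star, v_sag = v_sag_star,
                 steps = per, degree = deg),
            class = "pk_sag_fit")
}

#' @export
print.pk_sag_fit <- function(x, ...) {
  cat(sprintf("Sag index: %.3f at I* = %.1f pA (V_hyp %.1f, V_sag %.1f mV)\n",
              x$sag_index, x$i_star, x$v_hyp, x$v_sag))
  invisible(x)
}

sweep_dvdt <- function(sweep) {
  v <- sweep$samples
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * sweep$dt)
  d[1] <- (v[2] - v[1]) / sweep$dt
  d[n] <- (v[n] - v[n - 1]) / sweep$dt
  d * 1e-3  # mV/s -> mV/ms
}

#' Detect action potentials by the 10 mV/ms slope criterion
#'
#' A spike onset is each upward crossing of `dV/dt = slope_criterion`
#' (central-difference derivative, crossing time and voltage linearly
#' interpolated between samples) that is followed within `peak_window_ms` by
#' a local maximum exceeding the onset voltage by at least
#' `min_peak_above` mV. Spikes are time-stamped at the peak; crossings within
#' `refractory_ms` of the previous accepted onset, or before its peak, are
#' ignored. An empty train is a valid result.
#'
#' @param sweep Current-clamp [sweep_trace()] with `dt <= 1e-4` s.
#' @param slope_criterion Onset slope (mV/ms), default 10.
#' @param min_peak_above Required peak height above onset voltage (mV).
#' @param peak_window_ms Window after onset in which the peak must occur (ms).
#' @param refractory_ms Refractory exclusion after an accepted onset (ms).
#' @return An object of class `pk_spike_train`: list with `spike_times`
#'   (peak times, s), `onset_times`, `onset_voltages`, `isis_ms`, and the
#'   stimulus `window` (s).
#' @export
detect_spikes <- function(sweep, slope_criterion = 10, min_peak_above = 20,
                          peak_window_ms = 2, refractory_ms = 1) {
  stopifnot(inherits(sweep, "pk_sweep"), sweep$clamp_mode == "current_clamp")
  if (sweep$dt > 1e-4) stop("sampling too coarse for spike detection (need dt <= 1e-4 s)", call. = FALSE)
  v <- sweep$samples
  t <- sweep_times(sweep)
  d <- sweep_dvdt(sweep)
  n <- length(v)

  cross <- which(d[-n] <= slope_criterion & d[-1] > slope_criterion)
  peak_w <- round(peak_window_ms * 1e-3 / sweep$dt)

  onset_t <- onset_v <- peak_t <- numeric(0)
  last_onset <- -Inf
  last_peak <- -Inf
  for (k in cross) {
    frac <- (slope_criterion - d[k]) / (d[k + 1] - d[k])
    tc <- t[k] + frac * sweep$dt
    if (tc - last_onset < refractory_ms * 1e-3 || tc < last_peak) next
    vc <- v[k] + frac * (v[k + 1] - v[k])
    hi <- min(n, k + peak_w)
    seg <- v[(k + 1):hi]
    pk <- which.max(seg)
    if (seg[pk] < vc + min_peak_above) next
    # require a genuine local maximum (not a rising edge truncated by window)
    pk_idx <- k + pk
    if (pk_idx < n && v[pk_idx + 1] > v[pk_idx]) next
    onset_t <- c(onset_t, tc)
    onset_v <- c(onset_v, vc)
    peak_t <- c(peak_t, t[pk_idx])
    last_onset <- tc
    last_peak <- t[pk_idx]
  }
  window <- if (!is.null(sweep$stim)) {
    c(sweep$stim$onset, sweep$stim$onset + sweep$stim$duration)
  } else c(0, sweep_duration(sweep))
  structure(list(spike_times = peak_t, onset_times = onset_t,
                 onset_voltages = onset_v,
                 isis_ms = if (length(peak_t) > 1) diff(peak_t) * 1e3 else numeric(0),
                 window = window),
            class = "pk_spike_train")
}

#' @export
print.pk_spike_train <- function(x, ...) {
  cat(sprintf("<pk_spike_train> %d spikes in [%.3g, %.3g] s\n",
              length(x$spike_times), x$window[1], x$window[2]))
  invisible(x)
}

#' @export
as_tibble.pk_spike_train <- function(x, ...) {
  tibble::tibble(spike = seq_along(x$spike_times), t_onset = x$onset_times,
                 t_peak = x$spike_times, v_onset = x$onset_voltages)
}

#' Action-potential waveform features for one detected spike
#'
#' Threshold is the voltage at the interpolated 10 mV/ms crossing; amplitude
#' is peak minus threshold; half-width is the time between the two crossings
#' of threshold + amplitude/2 (linearly interpolated between samples);
#' maximal rise and decay slopes are the dV/dt extrema between onset and the
#' AHP trough; the AHP is threshold minus the most negative potential within
#' 20 ms of the peak (or up to the next spike onset). If the sweep ends
#' before the AHP window completes, `ahp` is returned as `NA`.
#'
#' @param sweep The current-clamp [sweep_trace()] the spikes came from.
#' @param spikes A [detect_spikes()] result.
#' @param which Index of the spike to measure (default the first, as
#'   conventional for rheobase AP characterization).
#' @param ahp_window_ms AHP search window after the peak (ms).
#' @return One-row tibble: `threshold` (mV), `amplitude` (mV), `half_width`
#'   (ms), `max_rise`, `max_decay` (mV/ms), `ahp` (mV, positive depth below
#'   threshold).
#' @export
ap_features <- function(sweep, spikes, which = 1, ahp_window_ms = 20) {
  stopifnot(inherits(spikes, "pk_spike_train"), which >= 1,
            which <= length(spikes$spike_times))
  v <- sweep$samples
  t <- sweep_times(sweep)
  d <- sweep_dvdt(sweep)
  dt <- sweep$dt

  thr <- spikes$onset_voltages[[which]]
  t_on <- spikes$onset_times[[which]]
  t_pk <- spikes$spike_times[[which]]
  i_pk <- round(t_pk / dt) + 1L
  v_pk <- v[i_pk]
  amp <- v_pk - thr

  # AHP trough: peak -> min(peak + window, next onset, sweep end)
  t_stop <- t_pk + ahp_window_ms * 1e-3
  truncated <- FALSE
  if (which < length(spikes$spike_times)) {
    t_stop <- min(t_stop, spikes$onset_times[[which + 1]])
  }
  if (t_stop > t[length(t)]) {
    t_stop <- t[length(t)]
    truncated <- TRUE
  }
  i_stop <- min(length(v), round(t_stop / dt) + 1L)
  trough_rel <- which.min(v[i_pk:i_stop])
  i_tr <- i_pk + trough_rel - 1L
  ahp <- if (truncated && i_tr == i_stop) NA_real_ else thr - v[i_tr]

  # half-width: crossings of threshold + amplitude/2 around the peak
  level <- thr + amp / 2
  i_on <- max(1L, floor(t_on / dt) + 1L)
  rise_seg <- i_on:i_pk
  ri <- rise_seg[which(v[rise_seg] < level & v[rise_seg + 1L] >= level)]
  fall_seg <- i_pk:(i_tr - 1L)
  fi <- fall_seg[which(v[fall_seg] >= level & v[fall_seg + 1L] < level)]
  half_width <- NA_real_
  if (length(ri) > 0 && length(fi) > 0) {
    ri <- ri[[length(ri)]]
    fi <- fi[[1]]
    t_r <- t[ri] + dt * (level - v[ri]) / (v[ri + 1L] - v[ri])
    t_f <- t[fi] + dt * (level - v[fi]) / (v[fi + 1L] - v[fi])
    half_width <- (t_f - t_r) * 1e3
  }

  seg <- i_on:i_tr
  tibble::tibble(threshold = thr, amplitude = amp, half_width = half_width,
                 max_rise = max(d[seg]), max_decay = min(d[seg]), ahp = ahp)
}

#' Firing frequency and adaptation ratio of a spike train
#'
#' Firing frequency is the spike count over the stimulus window duration.
#' The adaptation ratio is the mean of the last interspike intervals divided
#' by the first: the last 3 ISIs when at least 5 exist, the last 2 with 3-4
#' ISIs, and the single last ISI with only 2 (values below 1 indicate
#' late-train acceleration, above 1 accommodation). With fewer than 3 spikes
#' the ratio is `NA` but the frequency is still returned.
#'
#' @param spikes A [detect_spikes()] result.
#' @return One-row tibble: `n_spikes`, `firing_frequency` (Hz),
#'   `adaptation_ratio`.
#' @export
train_stats <- function(spikes) {
  stopifnot(inherits(spikes, "pk_spike_train"))
  dur <- diff(spikes$window)
  freq <- length(spikes$spike_times) / dur
  isis <- spikes$isis_ms
  adapt <- if (length(isis) >= 2) {
    k <- if (length(isis) >= 5) 3 else if (length(isis) >= 3) 2 else 1
    mean(utils::tail(isis, k)) / isis[[1]]
  } else NA_real_
  tibble::tibble(n_spikes = length(spikes$spike_times),
                 firing_frequency = freq, adaptation_ratio = adapt)
}

#' Assemble the full intrinsic-property record for one cell
#'
#' Convenience wrapper running the individual estimators over the standard
#' protocol sweeps and returning one tidy row per cell, mirroring the
#' conventional intrinsic-parameter table (resting potential, input
#' resistance, time constant, capacitance, sag index, first-spike waveform
#' features, firing frequency and adaptation ratio).
#'
#' @param passive_sweeps Current-step family for [input_resistance()].
#' @param tau_sweeps Repeated identical pulses for [time_constant()].
#' @param sag_sweeps Hyperpolarizing family for [sag_index()]; `NULL` skips.
#' @param train_sweep 2x-rheobase train sweep for [detect_spikes()] /
#'   [train_stats()]; `NULL` skips.
#' @param rheobase_sweep Just-suprathreshold sweep whose first AP is measured
#'   by [ap_features()]; defaults to `train_sweep`.
#' @param cell_id Label carried into the output row.
#' @return One-row tibble of membrane properties.
#' @export
membrane_properties <- function(passive_sweeps, tau_sweeps,
                                sag_sweeps = NULL, train_sweep = NULL,
                                rheobase_sweep = train_sweep,
                                cell_id = "cell_1") {
  v_rest <- resting_potential(passive_sweeps[[1]])
  rm_fit <- input_resistance(passive_sweeps)
  tau_fit <- time_constant(tau_sweeps, r_m = rm_fit$r_m)
  sag <- if (!is.null(sag_sweeps)) sag_index(sag_sweeps, v_rest = v_rest)$sag_index else NA_real_

  feats <- tibble::tibble(threshold = NA_real_, amplitude = NA_real_,
                          half_width = NA_real_, max_rise = NA_real_,
                          max_decay = NA_real_, ahp = NA_real_)
  freq <- adapt <- NA_real_
  if (!is.null(rheobase_sweep)) {
    sp <- detect_spikes(rheobase_sweep)
    if (length(sp$spike_times) > 0) feats <- ap_features(rheobase_sweep, sp, which = 1)
  }
  if (!is.null(train_sweep)) {
    st <- train_stats(detect_spikes(train_sweep))
    freq <- st$firing_frequency
    adapt <- st$adaptation_ratio
  }
  tibble::tibble(
    cell_id = cell_id, v_rest = v_rest, r_m = rm_fit$r_m,
    tau_m = tau_fit$tau_ms, c_m = tau_fit$c_m, sag_index = sag,
    spike_threshold = feats$threshold, spike_amplitude = feats$amplitude,
    half_width = feats$half_width, max_rise_slope = feats$max_rise,
    max_decay_slope = feats$max_decay, ahp = feats$ahp,
    firing_frequency = freq, adaptation_ratio = adapt
  )
}
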