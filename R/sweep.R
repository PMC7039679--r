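#' Construct a single recorded sweep
#'
#' A sweep is one uniformly sampled trace together with the metadata needed to
#' interpret it: sampling interval, clamp mode (which fixes the units:
#' millivolts in current clamp and field mode, picoamps in voltage clamp),
#' holding level, and an optional stimulus protocol. Inward currents are
#' negative, outward currents positive, throughout the package. Time is in
#' seconds everywhere; unit conversions happen only at the I/O boundary.
#'
#' @param samples Numeric vector of samples (mV for current clamp / field, pA
#'   for voltage clamp). Must be non-empty and finite.
#' @param dt Sampling interval in seconds (e.g. `5e-5` for 20 kHz).
#' @param clamp_mode One of `"current_clamp"`, `"voltage_clamp"`, `"field"`.
#' @param holding Holding potential (mV, voltage clamp) or bias current (pA,
#'   current clamp). May be `NA`.
#' @param stim Optional [step_protocol()] describing the stimulus.
#' @param sweep_id Character label for the sweep.
#' @return An object of class `pk_sweep`.
#' @examples
#' sw <- sweep_trace(rep(-60, 2000), dt = 5e-5, clamp_mode = "current_clamp")
#' sweep_duration(sw)
#' @export
sweep_trace <- function(samples, dt, clamp_mode = c("current_clamp", "voltage_clamp", "field"),
                        holding = NA_real_, stim = NULL, sweep_id = "sweep_1") {
  clamp_mode <- match.arg(clamp_mode)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "pk_step_protocol"))
    if (stim$onset + stim$duration > length(samples) * dt + 1e-12) {
      stop("stimulus extends past the end of the sweep", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, dt = dt, clamp_mode = clamp_mode,
         holding = as.numeric(holding), stim = stim,
         sweep_id = as.character(sweep_id)),
    class = "pk_sweep"
  )
}

#' Stimulus step / train protocol metadata
#'
#' @param onset Step onset (s), `>= 0`.
#' @param duration Step duration (s).
#' @param amplitude Step amplitude: pA in current clamp, mV in voltage clamp.
#' @param pulse_times Optional strictly increasing vector of presynaptic
#'   AP / light-pulse onset times (s) for train protocols.
#' @param pulse_rate Optional train rate (Hz).
#' @return An object of class `pk_step_protocol`.
#' @export
step_protocol <- function(onset, duration, amplitude = NA_real_,
                          pulse_times = NULL, pulse_rate = NA_real_) {
  stopifnot(is.numeric(onset), onset >= 0, is.numeric(duration), duration >= 0)
  if (!is.null(pulse_times)) {
    pulse_times <- as.numeric(pulse_times)
    if (length(pulse_times) > 1L && any(diff(pulse_times) <= 0)) {
      stop("`pulse_times` must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(onset = as.numeric(onset), duration = as.numeric(duration),
         amplitude = as.numeric(amplitude), pulse_times = pulse_times,
         pulse_rate = as.numeric(pulse_rate)),
    class = "pk_step_protocol"
  )
}

#' Bundle sweeps from one cell into a recording
#'
#' @param sweeps A list of [sweep_trace()] objects (all with compatible clamp
#'   modes is not enforced across modes: a recording may mix current-clamp and
#'   voltage-clamp families, but units are always fixed by each sweep's mode).
#' @param internal,external Named numeric vectors of salt concentrations (mM),
#'   e.g. `c("K-gluconate" = 130, "KCl" = 5)`. Used by [nernst()].
#' @param temperature Bath temperature in degrees Celsius (20-40).
#' @param metadata Free-form named list of labels.
#' @return An object of class `pk_recording`.
#' @export
cell_recording <- function(sweeps, internal = NULL, external = NULL,
                           temperature = 33, metadata = list()) {
  if (inherits(sweeps, "pk_sweep")) sweeps <- list(sweeps)
  stopifnot(is.list(sweeps))
  if (length(sweeps) == 0L) stop("a recording needs at least one sweep", call. = FALSE)
  ok <- vapply(sweeps, inherits, logical(1), what = "pk_sweep")
  if (!all(ok)) stop("all elements of `sweeps` must be pk_sweep objects", call. = FALSE)
  if (!is.na(temperature) && (temperature < 20 || temperature > 40)) {
    stop("`temperature` must lie within 20-40 degrees C", call. = FALSE)
  }
  for (sol in list(internal, external)) {
    if (!is.null(sol) && any(sol < 0)) stop("solution concentrations must be >= 0", call. = FALSE)
  }
  structure(
    list(sweeps = sweeps, internal = internal, external = external,
         temperature = temperature, metadata = metadata),
    class = "pk_recording"
  )
}

#' @export
print.pk_sweep <- function(x, ...) {
  unit <- sweep_units(x)
  cat(sprintf("<pk_sweep '%s'> %d samples @ %.6g kHz (%s, %s), %.4g s\n",
              x$sweep_id, length(x$samples), 1e-3 / x$dt, x$clamp_mode, unit,
              sweep_duration(x)))
  invisible(x)
}

#' @export
print.pk_recording <- function(x, ...) {
  cat(sprintf("<pk_recording> %d sweep(s), %.3g degC\n", length(x$sweeps), x$temperature))
  invisible(x)
}

#' Duration of a sweep in seconds
#' @param sweep A [sweep_trace()] object.
#' @export
sweep_duration <- function(sweep) length(sweep$samples) * sweep$dt

#' Sample times of a sweep (seconds, first sample at t = 0)
#' @param sweep A [sweep_trace()] object.
#' @export
sweep_times <- function(sweep) (seq_along(sweep$samples) - 1) * sweep$dt

sweep_units <- function(sweep) {
  switch(sweep$clamp_mode, current_clamp = "mV", voltage_clamp = "pA", field = "mV")
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.pk_sweep <- function(x, ...) {
  tibble::tibble(sweep_id = x$sweep_id, time = sweep_times(x), value = x$samples)
}

#' @export
as_tibble.pk_recording <- function(x, ...) {
  dplyr::bind_rows(lapply(x$sweeps, as_tibble))
}

#' Plot a sweep or a recording
#'
#' @param object A `pk_sweep` or `pk_recording`.
#' @param ... Unused.
#' @return A ggplot object (time on x, signal on y, one facet per sweep for
#'   recordings).
#' @importFrom ggplot2 autoplot ggplot aes geom_line labs facet_wrap
#' @export
autoplot.pk_sweep <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = sweep_units(object), title = object$sweep_id)
}

#' @rdname autoplot.pk_sweep
#' @export
autoplot.pk_recording <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sweep_id, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "signal")
}
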