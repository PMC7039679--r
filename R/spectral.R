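#' Welch power spectrum of a field-potential epoch
#'
#' Averaged modified periodogram: the epoch is split into Hann-windowed
#' segments (default 1 s with 50% overlap), each linearly detrended, and the
#' one-sided power spectral densities are averaged. The normalization is
#' chosen so the integral of the density over frequency equals the
#' time-domain variance (Parseval). The spectral peak is searched within
#' `peak_band` (default 10-100 Hz) and the gamma band power is the
#' integrated density over `band` (inclusive 20-80 Hz by default).
#'
#' @param sweep A [sweep_trace()] (any clamp mode; conventionally `field`),
#'   at least one segment long.
#' @param segment_s Segment length (s).
#' @param overlap Fractional overlap between segments.
#' @param peak_band Frequency range searched for the peak (Hz).
#' @param band Band-power integration range (Hz), inclusive.
#' @return An object of class `pk_spectrum`: list with `frequencies` (Hz),
#'   `psd` (signal units squared per Hz), `peak_frequency`, `peak_power`
#'   (density at the peak), `band_power` (integrated over `band`),
#'   `band_power_density` (mean density over `band`), and the settings.
#' @export
power_spectrum <- function(sweep, segment_s = 1, overlap = 0.5,
                           peak_band = c(10, 100), band = c(20, 80)) {
  stopifnot(inherits(sweep, "pk_sweep"))
  x <- sweep$samples
  fs <- 1 / sweep$dt
  L <- round(segment_s * fs)
  if (length(x) < L) stop("epoch shorter than one Welch segment", call. = FALSE)
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  k <- seq_len(L)
  w <- 0.5 * (1 - cos(2 * pi * (k - 1) / (L - 1)))
  scale <- 1 / (fs * sum(w^2))

  acc <- numeric(L %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)]
    seg <- stats::residuals(stats::lm.fit(cbind(1, k), seg))  # linear detrend
    X <- stats::fft(seg * w)
    p <- Mod(X[seq_len(L %/% 2 + 1)])^2 * scale
    p[2:(L %/% 2)] <- 2 * p[2:(L %/% 2)]  # one-sided (DC and Nyquist not doubled)
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freqs <- (seq_along(psd) - 1) * fs / L
  df <- fs / L

  in_peak <- freqs >= peak_band[1] & freqs <= peak_band[2]
  i_pk <- which(in_peak)[which.max(psd[in_peak])]
  in_band <- freqs >= band[1] & freqs <= band[2]
  structure(list(frequencies = freqs, psd = psd,
                 peak_frequency = freqs[i_pk], peak_power = psd[i_pk],
                 band_power = sum(psd[in_band]) * df,
                 band_power_density = mean(psd[in_band]),
                 band = band, peak_band = peak_band,
                 segment_s = segment_s, overlap = overlap, fs = fs),
            class = "pk_spectrum")
}

#' @export
print.pk_spectrum <- function(x, ...) {
  cat(sprintf("<pk_spectrum> peak %.1f Hz (density %.3g), band power [%g-%g Hz] %.3g\n",
              x$peak_frequency, x$peak_power, x$band[1], x$band[2], x$band_power))
  invisible(x)
}

#' Illumination-locked modulation of gamma oscillations
#'
#' Compares matched epochs before, during, and after an illumination period:
#' during/pre and post/pre ratios of peak power and gamma band power, plus
#' peak-frequency shifts. A during/pre band-power ratio below
#' `suppressed_below` flags the oscillation as suppressed (the residual
#' ratio then reflects the noise floor rather than an oscillation).
#'
#' @param pre,during,post [power_spectrum()] summaries of matched epochs.
#' @param suppressed_below Band-power ratio below which the during epoch is
#'   flagged suppressed.
#' @return One-row tibble with the ratios, frequency shifts (Hz), and the
#'   `suppressed` flag.
#' @export
illumination_modulation <- function(pre, during, post,
                                    suppressed_below = 0.05) {
  for (obj in list(pre, during, post)) stopifnot(inherits(obj, "pk_spectrum"))
  if (pre$band_power == 0) stop("pre-illumination band power is zero", call. = FALSE)
  tibble::tibble(
    peak_power_ratio_during = during$peak_power / pre$peak_power,
    peak_power_ratio_post = post$peak_power / pre$peak_power,
    band_power_ratio_during = during$band_power / pre$band_power,
    band_power_ratio_post = post$band_power / pre$band_power,
    peak_shift_during = during$peak_frequency - pre$peak_frequency,
    peak_shift_post = post$peak_frequency - pre$peak_frequency,
    suppressed = during$band_power / pre$band_power < suppressed_below
  )
}
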