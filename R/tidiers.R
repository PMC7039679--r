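#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-observation table behind a fit (per-step
#' deflections, per-pulse release areas, per-frequency densities);
#' `glance()` returns the one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name patchkit-tidiers
NULL

#' @rdname patchkit-tidiers
#' @export
tidy.pk_rm_fit <- function(x, ...) x$steps

#' @rdname patchkit-tidiers
#' @export
glance.pk_rm_fit <- function(x, ...) {
  tibble::tibble(r_m = x$r_m, n_steps = nrow(x$steps),
                 n_included = sum(x$steps$included),
                 r_squared = summary(x$fit)$r.squared)
}

#' @rdname patchkit-tidiers
#' @export
glance.pk_tau_fit <- function(x, ...) {
  tibble::tibble(tau_ms = x$tau_ms, c_m = x$c_m, n_repeats = x$n_repeats)
}

#' @rdname patchkit-tidiers
#' @export
tidy.pk_sag_fit <- function(x, ...) x$steps

#' @rdname patchkit-tidiers
#' @export
glance.pk_sag_fit <- function(x, ...) {
  tibble::tibble(sag_index = x$sag_index, i_star = x$i_star,
                 v_hyp = x$v_hyp, v_sag = x$v_sag, poly_degree = x$degree)
}

#' @rdname patchkit-tidiers
#' @export
tidy.pk_spike_train <- function(x, ...) as_tibble(x)

#' @rdname patchkit-tidiers
#' @export
tidy.pk_release_rate <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$rate) - 1) * x$dt, rate = x$rate)
}

#' @rdname patchkit-tidiers
#' @export
tidy.pk_spectrum <- function(x, ...) {
  tibble::tibble(frequency = x$frequencies, power = x$psd)
}

#' @rdname patchkit-tidiers
#' @export
glance.pk_spectrum <- function(x, ...) {
  tibble::tibble(peak_frequency = x$peak_frequency, peak_power = x$peak_power,
                 band_power = x$band_power,
                 band_power_density = x$band_power_density)
}

#' Plot a release-rate histogram or a power spectrum
#'
#' @param object A `pk_release_rate` or `pk_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_release_rate <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "release rate (quanta/s)")
}

#' @rdname autoplot.pk_release_rate
#' @export
autoplot.pk_spectrum <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$frequency > 0 & df$frequency <= max(object$peak_band) * 1.5, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = 0, ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = "frequency (Hz)", y = "power density")
}
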