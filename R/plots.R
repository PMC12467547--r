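#' Plot an energy spectrum
#'
#' Relative per-degree energy contributions in dB against spatial frequency
#' (degree), one line per source depth, solid/dashed by orientation class.
#'
#' @param object an `energy_spectrum` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.energy_spectrum <- function(object, ...) {
  d <- dplyr::filter(object, is.finite(.data$db))
  if (!"orientation_class" %in% names(d))
    d <- dplyr::rename(d, orientation_class = "orientation")
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$radius_mm, .data$orientation_class, .data$l),
    db = to_db(mean(.data$fraction)), .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$l, y = .data$db,
    colour = factor(.data$radius_mm),
    linetype = .data$orientation_class
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "spatial frequency (degree l)",
                  y = "relative energy contribution (dB)",
                  colour = "source radius (mm)", linetype = "orientation") +
    ggplot2::theme_minimal()
}

#' Plot percentile envelopes of a spectral report
#'
#' @param object a `spectral_report` from [percentile_envelopes()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spectral_report <- function(object, ...) {
  d <- dplyr::filter(object, is.finite(.data$db))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$l, y = .data$db,
                                  colour = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (degree l)",
                  y = "relative energy contribution (dB)",
                  colour = "statistic") +
    ggplot2::theme_minimal()
}

#' Plot the depth dependence of the scalp energy
#'
#' @param gain the tibble returned by [energy_gain_curve()].
#' @return a ggplot object.
#' @export
plot_energy_gain <- function(gain) {
  ggplot2::ggplot(gain, ggplot2::aes(x = .data$radius_mm, y = .data$db,
                                     colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "source radius (mm)", y = "energy gain (dB)",
                  colour = "orientation") +
    ggplot2::theme_minimal()
}

#' Plot energy misestimation of discrete layouts against depth
#'
#' @param devs the tibble returned by [sampled_energy_deviation()].
#' @return a ggplot object.
#' @export
plot_sampling_deviation <- function(devs) {
  ggplot2::ggplot(devs, ggplot2::aes(x = .data$radius_mm,
                                     y = 100 * .data$rel_dev,
                                     colour = factor(.data$layout_n))) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::facet_wrap(~orientation_class) +
    ggplot2::labs(x = "source radius (mm)",
                  y = "relative energy deviation (%)",
                  colour = "sensors") +
    ggplot2::theme_minimal()
}
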