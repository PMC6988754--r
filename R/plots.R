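#' Plot an absorption spectrum
#'
#' Intensity against wavenumber, with the exciton sticks implied by the
#' lineshape. A secondary wavelength axis is drawn on top.
#'
#' @param object A `spectrum_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_model
#' @export
autoplot.spectrum_model <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_x_continuous(
      sec.axis = ggplot2::sec_axis(~ 1e7 / .x, name = "wavelength (nm)")
    ) +
    ggplot2::labs(
      x = expression(wavenumber ~ (cm^-1)),
      y = "intensity (arb. units)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an exciton stick spectrum
#'
#' Dipole strength per state against energy, coloured by band; bright
#' states (above the relative threshold) are emphasised.
#'
#' @param object An `exciton_states` object.
#' @param threshold_rel Bright threshold relative to the maximum
#'   strength.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exciton_states
#' @export
autoplot.exciton_states <- function(object, threshold_rel = 1e-6, ...) {
  df <- tidy(object, threshold_rel = threshold_rel)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$energy, xend = .data$energy,
    y = 0, yend = .data$dipole_strength,
    colour = .data$band, alpha = .data$bright
  )) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3), guide = "none") +
    ggplot2::labs(
      x = expression(energy ~ (cm^-1)),
      y = expression(dipole ~ strength ~ (D^2))
    ) +
    ggplot2::theme_minimal()
}

#' Plot descriptor distributions by pair class
#'
#' Overlaid histograms of the center-center distance or the orientation
#' factor kappa for the inter- and intra-chain pair classes.
#'
#' @param descriptors Tibble from [descriptor_distributions()].
#' @param var `"kappa"` or `"distance"`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_descriptor_distributions <- function(descriptors, var = c("kappa", "distance"),
                                          bins = 30) {
  var <- match.arg(var)
  ggplot2::ggplot(descriptors, ggplot2::aes(x = .data[[var]], fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(
      x = if (var == "kappa") expression(kappa) else "distance (Å)",
      y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Plot class-wise coupling statistics
#'
#' Means with 95% confidence intervals per class (and optional facet
#' variable), the standard comparison of inter- and intra-chain
#' couplings across complexes.
#'
#' @param stats Tibble from [class_statistics()].
#' @param x Column mapped to the x axis (default `"class"`).
#' @return A ggplot object.
#' @export
plot_coupling_stats <- function(stats, x = "class") {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data[[x]], y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2
    ) +
    ggplot2::labs(y = expression(coupling ~ (cm^-1))) +
    ggplot2::theme_minimal()
}
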