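#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FD LUT surface
#'
#' Log-amplitude (or phase) of the stored complex reflectance over the
#' bottom-layer absorption / scattering plane.
#'
#' @param object A `"fd_lut"`.
#' @param what `"amplitude"` or `"phase"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fd_lut <- function(object, what = c("amplitude", "phase"), ...) {
  what <- match.arg(what)
  df <- tidyr::expand_grid(mua = object$mua_grid, musp = object$musp_grid)
  df$value <- if (what == "amplitude") as.vector(t(log(Mod(object$R))))
              else as.vector(t(-Arg(object$R)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$musp, y = .data$mua,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (what == "amplitude") "ln A" else "phase (rad)") +
    ggplot2::labs(
      x = expression(mu[s] * minute ~ (mm^-1)),
      y = expression(mu[a] ~ (mm^-1)),
      title = sprintf("FD LUT, %s nm @ %.0f MHz",
                      object$metadata$wavelength_nm,
                      object$metadata$mod_freq_hz / 1e6))
}

#' Plot a g2 curve
#'
#' @param object A `"g2_curve"`.
#' @param ... Additional g2 curves to overlay (named).
#' @return A ggplot with a log-scaled delay axis.
#' @export
autoplot.g2_curve <- function(object, ...) {
  extra <- list(...)
  df <- dplyr::mutate(as_tibble(object), curve = "g2")
  for (nm in names(extra))
    df <- dplyr::bind_rows(df, dplyr::mutate(as_tibble(extra[[nm]]),
                                             curve = nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_s, y = .data$g2,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ (s)), y = expression(g[2](tau)))
}

#' Plot a sensitivity report
#'
#' Replicate-mean sensitivities (%/%) per perturbed parameter and output.
#'
#' @param object A `"sensitivity_result"` or the output of
#'   [sensitivity_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  rep <- if ("sensitivity_mean" %in% names(object)) object
         else sensitivity_report(object)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$parameter,
                                    y = .data$sensitivity_mean,
                                    fill = .data$output)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$sensitivity_mean - .data$sensitivity_se,
      ymax = .data$sensitivity_mean + .data$sensitivity_se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "sensitivity (%/%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a fitted measurement time series
#'
#' Long-format line plot of recovered per-frame parameters (one facet per
#' parameter), optionally overlaid with the generating truth of a
#' synthetic dataset.
#'
#' @param fits Tibble from [fit_timeseries()] /
#'   [hemodynamics_from_fits()].
#' @param truth Optional truth tibble with `time_s` and matching columns.
#' @param parameters Columns to show (default: the recovered optical and
#'   hemodynamic parameters present).
#' @return A ggplot.
#' @export
plot_timeseries <- function(fits, truth = NULL, parameters = NULL) {
  parameters <- parameters %||% intersect(
    c("mua_730", "mua_830", "musp_730", "musp_830", "bfi",
      "oxy_uM", "deoxy_uM", "total_uM", "sto2_pct", "mro2"),
    names(fits))
  long <- tidyr::pivot_longer(fits[, c("time_s", parameters)],
                              -"time_s", names_to = "parameter")
  long$source <- "recovered"
  if (!is.null(truth)) {
    tl <- tidyr::pivot_longer(
      truth[, intersect(c("time_s", parameters), names(truth))],
      -"time_s", names_to = "parameter")
    tl$source <- "truth"
    long <- dplyr::bind_rows(long, tl)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
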