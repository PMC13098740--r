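#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FD fit
#'
#' One row per recovered parameter, broom-style.
#'
#' @param x An `"fd_fit"` from [invert_fd()].
#' @param ... Unused.
#' @return Tibble with `wavelength_nm`, `term`, `estimate`, `boundary`.
#' @export
tidy.fd_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) tibble(
    wavelength_nm = rep(x$wavelength_nm[i], 2),
    term = c("mua", "musp"),
    estimate = c(x$mua[i], x$musp[i]),
    boundary = c(x$boundary_mua[i], x$boundary_musp[i])
  ))
}

#' @param x An `"fd_fit"`.
#' @param ... Unused.
#' @rdname tidy.fd_fit
#' @export
glance.fd_fit <- function(x, ...) {
  tibble(n_wavelengths = nrow(x),
         objective_total = sum(x$objective),
         any_boundary = any(x$boundary_mua | x$boundary_musp),
         model_tag = attr(x, "model_tag") %||% "multi_layer")
}

#' Tidy a DCS fit
#'
#' @param x A `"dcs_fit"` from [invert_dcs()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `boundary`.
#' @export
tidy.dcs_fit <- function(x, ...) {
  tibble(term = c("bfi", "beta"),
         estimate = c(x$bfi, x$beta),
         boundary = c(x$boundary_bfi, FALSE))
}

#' @rdname tidy.dcs_fit
#' @export
glance.dcs_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, boundary_bfi = x$boundary_bfi)
}

#' Tidy a sensitivity result
#'
#' @param x A `"sensitivity_result"` from [run_sensitivity()].
#' @param ... Unused.
#' @return The aggregated [sensitivity_report()] tibble.
#' @export
tidy.sensitivity_result <- function(x, ...) sensitivity_report(x)
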