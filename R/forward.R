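#' Beer-Lambert absorption weights for a photon batch
#'
#' White-Monte-Carlo absorption: each detected photon's weight is its exit
#' weight attenuated by `exp(-sum_j mua_j * L_j)` over the recorded
#' per-layer pathlengths.
#'
#' @param batch A `photon_batch` from [run_layered_mc()].
#' @param mua_per_layer Absorption coefficients (mm^-1), one per layer.
#' @return Numeric weight vector, one entry per detected photon.
#' @export
absorption_weights <- function(batch, mua_per_layer) {
  if (length(mua_per_layer) != ncol(batch$L))
    stop_bad_arg("`mua_per_layer` length must equal the number of layers")
  if (any(mua_per_layer < 0)) stop_bad_arg("`mua_per_layer` must be >= 0")
  batch$exit_weight * exp(-drop(batch$L %*% mua_per_layer))
}

#' Photon time-of-flight histogram
#'
#' Arrival times are computed from per-layer pathlengths and refractive
#' indices, `t = sum_j n_j L_j / c`, then binned. Total weight is conserved
#' by construction.
#'
#' @param batch A `photon_batch`.
#' @param weights Photon weights, typically from [absorption_weights()].
#' @param bin_width_ns Bin width in ns.
#' @param t_max_ns Histogram upper edge in ns; photons beyond it land in the
#'   last bin so that weight is conserved.
#' @return Tibble with class `"tof_histogram"`: columns `t_mid_ns`,
#'   `weight`, plus bin-edge attributes.
#' @export
tof_histogram <- function(batch, weights, bin_width_ns = 0.01,
                          t_max_ns = 12) {
  if (bin_width_ns <= 0) stop_bad_arg("`bin_width_ns` must be > 0")
  t_ns <- photon_times_ns(batch)
  edges <- seq(0, t_max_ns, by = bin_width_ns)
  if (max(edges) < t_max_ns) edges <- c(edges, t_max_ns)
  idx <- pmin(findInterval(t_ns, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  idx[idx < 1L] <- 1L
  w <- vapply(split(weights, factor(idx, levels = seq_len(length(edges) - 1L))),
              sum, numeric(1))
  out <- tibble(t_mid_ns = (edges[-1] + edges[-length(edges)]) / 2,
                weight = unname(w))
  structure(out[out$weight > 0 | seq_len(nrow(out)) == 1, ],
            bin_edges_ns = edges,
            class = c("tof_histogram", class(tibble())))
}

# per-photon arrival times in ns
photon_times_ns <- function(batch) {
  drop(batch$L %*% batch$n_per_layer) / .C_MM_PER_NS
}

#' Complex frequency-domain reflectance from a time-of-flight histogram
#'
#' Fourier transform of the photon time-of-flight distribution:
#' `R(omega) = sum_bins weight * exp(-i omega t)`. The reported phase is
#' `-Arg(R)` so that phase is positive and grows with modulation frequency,
#' scattering and distance (conventional FD-NIRS sign).
#'
#' @param hist A `"tof_histogram"`.
#' @param mod_freq_hz Modulation frequency in Hz (>= 0).
#' @param wavelength,sds Metadata carried into the result (optional).
#' @return One-row tibble with class `"fd_reflectance"`: `wavelength_nm`,
#'   `mod_freq_hz`, `sds_mm`, `amplitude`, `phase_rad`.
#' @export
fd_reflectance <- function(hist, mod_freq_hz, wavelength = NA_real_,
                           sds = NA_real_) {
  if (mod_freq_hz < 0) stop_bad_arg("`mod_freq_hz` must be >= 0")
  omega <- 2 * pi * mod_freq_hz * 1e-9  # rad per ns
  R <- sum(hist$weight * exp(-1i * omega * hist$t_mid_ns))
  structure(tibble(wavelength_nm = wavelength, mod_freq_hz = mod_freq_hz,
                   sds_mm = sds, amplitude = Mod(R),
                   phase_rad = -Arg(R)),
            class = c("fd_reflectance", class(tibble())))
}

# Direct (un-binned equivalent) complex reflectance from a batch; used by
# the LUT builder where times are quantized once to the TOF bin midpoints so
# the result is identical to fd_reflectance() on the histogram.
fd_from_batch <- function(batch, mua_per_layer, mod_freq_hz,
                          bin_width_ns = 0.01) {
  w <- absorption_weights(batch, mua_per_layer)
  t_ns <- quantize_times(photon_times_ns(batch), bin_width_ns)
  omega <- 2 * pi * mod_freq_hz * 1e-9
  sum(w * exp(-1i * omega * t_ns))
}

quantize_times <- function(t_ns, bin_width_ns) {
  (floor(t_ns / bin_width_ns) + 0.5) * bin_width_ns
}

#' Electric-field autocorrelation from a photon batch
#'
#' Brownian-dynamics correlation transfer: each detected photon contributes
#' `w_s * exp(-(1/3) * sum_j Y_sj * k0_j^2 * 6 * BFi_j * tau)`, where `Y` is
#' the per-layer dimensionless momentum transfer, `k0_j = 2 pi n_j / lambda`
#' the in-medium optical wavenumber and `BFi_j` the per-layer blood flow
#' index (mean-square displacement `6 BFi tau`). The curve is normalized to
#' `g1(0) = 1`.
#'
#' @param batch A `photon_batch`.
#' @param mua_per_layer Per-layer absorption (mm^-1) applied as Beer
#'   weights.
#' @param bfi_per_layer Per-layer blood flow indices (mm^2/s), >= 0.
#' @param tau Delay grid in seconds.
#' @param wavelength Optical wavelength in nm for `k0`.
#' @return Tibble with class `"g1_curve"`: columns `tau_s`, `g1`.
#' @export
g1_from_batch <- function(batch, mua_per_layer, bfi_per_layer,
                          tau = default_tau_grid(), wavelength = 850) {
  if (any(bfi_per_layer < 0)) stop_bad_arg("`bfi_per_layer` must be >= 0")
  if (length(bfi_per_layer) != ncol(batch$Y))
    stop_bad_arg("`bfi_per_layer` length must equal the number of layers")
  w <- absorption_weights(batch, mua_per_layer)
  k0 <- 2 * pi * batch$n_per_layer / (wavelength * 1e-6)  # mm^-1
  decay_rate <- drop(batch$Y %*% (2 * k0^2 * bfi_per_layer))  # per second
  G1 <- vapply(tau, function(tt) sum(w * exp(-decay_rate * tt)), numeric(1))
  structure(tibble(tau_s = tau, g1 = G1 / sum(w)),
            wavelength_nm = wavelength,
            class = c("g1_curve", class(tibble())))
}

#' Siegert relation
#'
#' Converts a normalized field autocorrelation into the normalized intensity
#' autocorrelation, `g2(tau) = 1 + beta * g1(tau)^2`, with `beta` the
#' instrument coherence factor (0.45 for the phantom configuration, ~0.35
#' in vivo).
#'
#' @param g1 A `"g1_curve"` tibble (columns `tau_s`, `g1`) or numeric
#'   vector.
#' @param beta Coherence factor in `[0, 1]`.
#' @return Tibble with class `"g2_curve"`: columns `tau_s`, `g2`, with
#'   attribute `beta`; or a numeric vector when `g1` is numeric.
#' @export
siegert <- function(g1, beta) {
  if (beta < 0 || beta > 1) stop_bad_arg("`beta` must be in [0, 1]")
  if (is.numeric(g1)) return(1 + beta * g1^2)
  structure(tibble(tau_s = g1$tau_s, g2 = 1 + beta * g1$g1^2),
            beta = beta,
            class = c("g2_curve", class(tibble())))
}
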