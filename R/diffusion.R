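#' Semi-infinite diffusion-theory reflectance (frequency domain)
#'
#' Closed-form extrapolated-boundary solution for the diffuse reflectance of
#' a homogeneous semi-infinite medium, used as an independent oracle for the
#' Monte Carlo engine and as an optional analytic single-layer inverse. The
#' solution places an isotropic source at depth `z0 = 1/(mua + musp)` and an
#' image source above the extrapolated boundary at `zb = 2 A D`, with `A`
#' from the effective internal reflection coefficient of the index mismatch:
#'
#' `R(rho) = (1/4pi) [ z0 (k + 1/r1) exp(-k r1)/r1^2
#'                   + (z0 + 2 zb)(k + 1/r2) exp(-k r2)/r2^2 ]`
#'
#' with complex `k = sqrt((mua + i omega / v) / D)`, `D = 1/(3 musp)`.
#'
#' @param mua Absorption coefficient, mm^-1.
#' @param musp Reduced scattering coefficient, mm^-1 (diffusive regime,
#'   `musp >> mua`).
#' @param n Refractive index of the medium.
#' @param rho Source-detector separation, mm.
#' @param mod_freq_hz Modulation frequency, Hz (0 gives the steady state).
#' @param n_ambient Ambient refractive index above the surface.
#' @return Complex reflectance per mm^2 per launched photon. Use `Mod()`
#'   and `-Arg()` for amplitude and (positive) phase.
#' @export
diffusion_fd_semi_infinite <- function(mua, musp, n, rho, mod_freq_hz = 0,
                                       n_ambient = 1) {
  D <- 1 / (3 * musp)
  v <- .C_MM_PER_NS * 1e9 / n  # mm/s
  k <- sqrt((mua + 2i * pi * mod_freq_hz / v) / D)
  z0 <- 1 / (mua + musp)
  zb <- 2 * A_internal_reflection(n / n_ambient) * D
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (z0 * (k + 1 / r1) * exp(-k * r1) / r1^2 +
     (z0 + 2 * zb) * (k + 1 / r2) * exp(-k * r2) / r2^2) / (4 * pi)
}

# Groenhuis polynomial for the internal-reflection parameter A(n_rel)
A_internal_reflection <- function(n_rel) {
  if (abs(n_rel - 1) < 1e-12) return(1)
  reff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + reff) / (1 - reff)
}

#' Annulus-averaged diffusion reflectance
#'
#' Averages [diffusion_fd_semi_infinite()] over the detector annulus
#' `[sds - hw, sds + hw]`, area-weighted, for like-for-like comparison with
#' the Monte Carlo annulus detector.
#'
#' @inheritParams diffusion_fd_semi_infinite
#' @param sds Annulus centre radius, mm.
#' @param hw Annulus half-width, mm.
#' @return Complex annulus-averaged reflectance per mm^2.
#' @export
diffusion_fd_annulus <- function(mua, musp, n, sds, hw, mod_freq_hz = 0,
                                 n_ambient = 1) {
  f <- function(r, part) {
    v <- diffusion_fd_semi_infinite(mua, musp, n, r, mod_freq_hz, n_ambient)
    if (part == "re") Re(v) * r else Im(v) * r
  }
  lo <- sds - hw; hi <- sds + hw
  re <- stats::integrate(function(r) vapply(r, f, numeric(1), part = "re"),
                         lo, hi, rel.tol = 1e-8)$value
  im <- stats::integrate(function(r) vapply(r, f, numeric(1), part = "im"),
                         lo, hi, rel.tol = 1e-8)$value
  complex(real = re, imaginary = im) / ((hi^2 - lo^2) / 2)
}

#' Correlation-diffusion oracle for a homogeneous semi-infinite medium
#'
#' Field autocorrelation under Brownian dynamics via the standard
#' substitution `mua -> mua + 2 musp k0^2 BFi tau` in the steady-state
#' diffusion solution, normalized so `g1(0) = 1`.
#'
#' @inheritParams diffusion_fd_semi_infinite
#' @param bfi Blood flow index, mm^2/s.
#' @param wavelength Optical wavelength, nm.
#' @param tau Delay grid, s.
#' @return Tibble with class `"g1_curve"`: columns `tau_s`, `g1`.
#' @export
diffusion_g1_semi_infinite <- function(mua, musp, n, rho, bfi,
                                       wavelength = 850,
                                       tau = default_tau_grid(),
                                       n_ambient = 1) {
  if (bfi < 0) stop_bad_arg("`bfi` must be >= 0")
  k0 <- 2 * pi * n / (wavelength * 1e-6)  # mm^-1
  G0 <- Re(diffusion_fd_semi_infinite(mua, musp, n, rho, 0, n_ambient))
  g1 <- vapply(tau, function(tt) {
    mua_dyn <- mua + 2 * musp * k0^2 * bfi * tt
    Re(diffusion_fd_semi_infinite(mua_dyn, musp, n, rho, 0, n_ambient)) / G0
  }, numeric(1))
  structure(tibble(tau_s = tau, g1 = g1),
            wavelength_nm = wavelength,
            class = c("g1_curve", class(tibble())))
}

#' Diffusion-theory mean photon time of flight
#'
#' Computed from the frequency derivative of the complex reflectance phase
#' at low modulation frequency; serves as an oracle for the first moment of
#' the Monte Carlo time-of-flight distribution.
#'
#' @inheritParams diffusion_fd_semi_infinite
#' @return Mean time of flight in ns.
#' @export
diffusion_mean_tof_ns <- function(mua, musp, n, rho, n_ambient = 1) {
  df <- 1e5  # Hz; well inside the linear-phase regime
  r0 <- diffusion_fd_semi_infinite(mua, musp, n, rho, 0, n_ambient)
  r1 <- diffusion_fd_semi_infinite(mua, musp, n, rho, df, n_ambient)
  (-Arg(r1 / r0)) / (2 * pi * df) * 1e9
}

#' N-layer frequency-domain diffusion reflectance (Hankel space)
#'
#' Planar multi-layer extension of the diffusion oracle: the
#' photon-density wave equation is solved analytically in cylindrical
#' Hankel space with a transfer (admittance) recursion through the layer
#' stack (matched inter-layer refractive indices; extrapolated boundary at
#' the surface; semi-infinite bottom layer), and the fluence at the surface
#' is inverted to real space by Gauss-Legendre panels between Bessel-zero
#' partitions, which controls the catastrophic cancellation of the
#' oscillatory integrand at large source-detector separations.
#'
#' Used as an independent cross-check of the layered Monte Carlo engine;
#' amplitudes are fluence-based and share an arbitrary scale, so compare
#' phases and amplitude ratios.
#'
#' @param mua,musp Per-layer coefficients (mm^-1), top to bottom.
#' @param thickness Thicknesses of all but the bottom layer (mm).
#' @param n Refractive index (single value; assumed common to all layers).
#' @param rho Source-detector separation, mm.
#' @param mod_freq_hz Modulation frequency, Hz.
#' @param n_ambient Ambient index above the surface.
#' @param s_max Upper limit of the Hankel variable (mm^-1).
#' @return Complex surface fluence (arbitrary scale).
#' @export
diffusion_fd_nlayer <- function(mua, musp, thickness, n = 1.4, rho = 25,
                                mod_freq_hz = 0, n_ambient = 1,
                                s_max = 15) {
  N <- length(mua)
  if (length(musp) != N || length(thickness) != N - 1)
    stop_bad_arg("need musp per layer and thickness for all but the bottom")
  D <- 1 / (3 * musp)
  v <- .C_MM_PER_NS * 1e9 / n
  w <- 2 * pi * mod_freq_hz
  zb <- 2 * A_internal_reflection(n / n_ambient) * D[1]
  z0 <- 1 / (mua[1] + musp[1])
  ctanh <- function(x) ifelse(Re(x) > 20, 1 + 0i, tanh(x))
  phi_tilde <- function(s) {
    vapply(s, function(ss) {
      k <- sqrt((mua + 1i * w / v) / D + ss^2)
      beta <- D[N] * k[N]
      if (N >= 3) {
        for (i in seq(N - 1, 2)) {   # middle layers, bottom up
          t <- ctanh(k[i] * thickness[i])
          beta <- D[i] * k[i] * (beta + D[i] * k[i] * t) /
            (D[i] * k[i] + beta * t)
        }
      }
      k1 <- k[1]; D1 <- D[1]
      bb <- beta / (D1 * k1)
      tX <- if (N == 1) 1 + 0i else ctanh(k1 * (thickness[1] - z0))
      r <- -k1 * (tX + bb) / (1 + bb * tX)
      cth <- 1 / ctanh(k1 * (z0 + zb))
      (1 / (D1 * k1 * cth - D1 * r)) * sinh(k1 * zb) / sinh(k1 * (z0 + zb))
    }, complex(1))
  }
  # oscillatory Hankel inversion: Gauss-Legendre between Bessel zeros
  breaks <- c(0, (seq_len(ceiling(s_max * rho / pi) + 1) - 0.25) * pi / rho)
  total <- 0 + 0i
  for (m in seq_len(length(breaks) - 1)) {
    gl <- pracma::gaussLegendre(12, breaks[m], breaks[m + 1])
    total <- total +
      sum(gl$w * phi_tilde(gl$x) * besselJ(gl$x * rho, 0) * gl$x)
  }
  total / (2 * pi)
}
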