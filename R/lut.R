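#' Look-up-table axes
#'
#' Grids over the bottom-layer (target tissue) properties. The reduced
#' scattering axis is simulated at a coarse 0.1 mm^-1 step over
#' 0.1-1.0 mm^-1 and densified by linear interpolation: step 0.001 mm^-1
#' for the complex FD reflectance and 0.05 mm^-1 for g2. The absorption
#' axis (0.01-0.2 mm^-1) is filled by Beer-Lambert reweighting of the white
#' Monte Carlo batches and is therefore cheap to evaluate densely. The BFi
#' axis is log-spaced over 0.1-40 x 10^-6 mm^2/s; BFi enters the field
#' autocorrelation analytically, so no interpolation is involved along it.
#'
#' @param musp_range,musp_step_coarse Simulated reduced-scattering axis
#'   (mm^-1).
#' @param musp_step_fd,musp_step_dcs Dense interpolation steps (mm^-1).
#' @param mua_range,mua_step Absorption axis (mm^-1).
#' @param bfi_range BFi axis range (mm^2/s).
#' @param bfi_n Number of log-spaced BFi nodes.
#' @return A list with class `"lut_axes"`.
#' @export
lut_axes <- function(musp_range = c(0.1, 1.0), musp_step_coarse = 0.1,
                     musp_step_fd = 0.001, musp_step_dcs = 0.05,
                     mua_range = c(0.01, 0.2), mua_step = 0.001,
                     bfi_range = c(0.1e-6, 40e-6), bfi_n = 121) {
  # grids built by index multiplication, not accumulation, so node counts
  # and coarse-in-dense containment are exact in floating point
  grid_seq <- function(from, to, by)
    from + by * seq(0, round((to - from) / by))
  ax <- list(
    musp_coarse = grid_seq(musp_range[1], musp_range[2], musp_step_coarse),
    musp_dense_fd = grid_seq(musp_range[1], musp_range[2], musp_step_fd),
    musp_dense_dcs = grid_seq(musp_range[1], musp_range[2], musp_step_dcs),
    mua_grid = grid_seq(mua_range[1], mua_range[2], mua_step),
    bfi_grid = exp(seq(log(bfi_range[1]), log(bfi_range[2]),
                       length.out = bfi_n))
  )
  stopifnot(all(diff(ax$musp_coarse) > 0), all(diff(ax$mua_grid) > 0))
  structure(ax, class = "lut_axes")
}

#' Run the Monte Carlo batches backing a LUT
#'
#' For each coarse reduced-scattering node of the bottom layer,
#' `n_repeats` independent-seed simulations are run (white in absorption)
#' and pooled. Upper layers are fixed by the medium template; the bottom
#' layer's absorption plays no role in transport, so the same batches serve
#' the whole absorption axis — and, for tissue templates whose upper-layer
#' scattering does not depend on skin tone, every skin tone.
#'
#' @param medium Template [layered_medium()]; its bottom-layer scattering is
#'   replaced node by node.
#' @param axes A [lut_axes()].
#' @param sim A [sim_config()]; `sim$n_photons` is the count per repeat and
#'   seeds are derived deterministically from `sim$seed`, node and repeat.
#' @param wavelength Wavelength (nm) for the upper-layer scattering
#'   properties.
#' @param n_repeats Independent simulations pooled per node.
#' @return List with class `"lut_batches"`: pooled `photon_batch` per
#'   coarse node plus the template and provenance.
#' @export
mc_lut_batches <- function(medium, axes, sim, wavelength, n_repeats = 10) {
  nodes <- axes$musp_coarse
  batches <- lapply(seq_along(nodes), function(i) {
    med_i <- set_bottom(medium, musp = nodes[i])
    reps <- lapply(seq_len(n_repeats), function(r) {
      sim_r <- sim
      sim_r$seed <- derive_seed(sim$seed, i, r)
      run_layered_mc(med_i, sim_r, wavelength)
    })
    b <- if (n_repeats > 1) pool_batches(reps) else reps[[1]]
    if (b$n_detected == 0)
      abort(sprintf("no detected photons at musp node %.3g", nodes[i]),
            class = "mldos_empty_node")
    b
  })
  structure(list(batches = batches, musp_coarse = nodes, medium = medium,
                 wavelength = wavelength, sim = sim, n_repeats = n_repeats),
            class = "lut_batches")
}

# complex FD reflectance per launched photon at one node over the mua grid;
# upper-layer mua fixed from the template, bottom mua swept
node_fd_over_mua <- function(batch, upper_mua, mua_grid, mod_freq_hz,
                             bin_width_ns = 0.01) {
  nl <- ncol(batch$L)
  w_upper <- batch$exit_weight *
    exp(-drop(batch$L[, -nl, drop = FALSE] %*% upper_mua))
  t_ns <- quantize_times(photon_times_ns(batch), bin_width_ns)
  omega <- 2 * pi * mod_freq_hz * 1e-9
  ph <- w_upper * exp(-1i * omega * t_ns)
  Lb <- batch$L[, nl]
  # [n_mua x ndet] %*% [ndet] in two real products
  E <- exp(-outer(mua_grid, Lb))
  drop(E %*% ph) / batch$n_launched
}

#' Build a frequency-domain reflectance LUT
#'
#' Maps bottom-layer `(mua, musp)` to the complex FD reflectance predicted
#' under the template's fixed upper layers. The absorption axis is filled by
#' Beer-Lambert reweighting of the pooled white-MC batches; the scattering
#' axis is linearly interpolated on the real and imaginary parts separately
#' from the coarse nodes to the dense axis.
#'
#' @inheritParams mc_lut_batches
#' @param mod_freq_hz Modulation frequency (Hz).
#' @param batches Optional precomputed [mc_lut_batches()] (so one batch set
#'   can back several LUTs, e.g. different skin tones or both FD and DCS).
#' @return A `"fd_lut"`: complex matrix `R` (`mua x musp_dense`), axes and
#'   regeneration metadata.
#' @export
build_fd_lut <- function(medium, axes, sim, wavelength, mod_freq_hz,
                         n_repeats = 10, batches = NULL) {
  if (is.null(batches))
    batches <- mc_lut_batches(medium, axes, sim, wavelength, n_repeats)
  props <- medium_properties(medium, wavelength)
  upper_mua <- props$mua[-nrow(props)]
  coarse <- vapply(batches$batches, function(b)
    node_fd_over_mua(b, upper_mua, axes$mua_grid, mod_freq_hz),
    complex(length(axes$mua_grid)))
  if (length(axes$mua_grid) == 1) coarse <- matrix(coarse, nrow = 1)
  # densify musp by linear interpolation of Re and Im per mua row
  dense <- t(apply(coarse, 1, function(row) {
    re <- approx(batches$musp_coarse, Re(row), xout = axes$musp_dense_fd)$y
    im <- approx(batches$musp_coarse, Im(row), xout = axes$musp_dense_fd)$y
    complex(real = re, imaginary = im)
  }))
  meta <- list(
    wavelength_nm = wavelength, mod_freq_hz = mod_freq_hz,
    sds_mm = sim$sds, half_width_mm = sim$detector_half_width,
    n_photons = sim$n_photons, n_repeats = batches$n_repeats,
    seed = sim$seed, mua_ref = sim$mua_ref,
    layers = medium$layer,
    upper_mua = upper_mua,
    medium_hash = object_md5(medium_properties(medium, wavelength)),
    created = "mldos"
  )
  structure(list(R = dense, mua_grid = axes$mua_grid,
                 musp_grid = axes$musp_dense_fd, metadata = meta),
            class = "fd_lut")
}

#' @export
print.fd_lut <- function(x, ...) {
  cat(sprintf("<fd_lut> %d mua x %d musp nodes, %s nm @ %.3g MHz, sds %.3g mm\n",
              length(x$mua_grid), length(x$musp_grid),
              x$metadata$wavelength_nm, x$metadata$mod_freq_hz / 1e6,
              x$metadata$sds_mm))
  invisible(x)
}

#' Query an FD LUT
#'
#' Bilinear interpolation of the complex reflectance (real and imaginary
#' parts separately) at arbitrary in-range `(mua, musp)`.
#'
#' @param lut A `"fd_lut"`.
#' @param mua,musp Query points (mm^-1), scalars.
#' @return One-row `fd_reflectance` tibble (amplitude per launched photon).
#' @export
lut_query_fd <- function(lut, mua, musp) {
  R <- bilinear_complex(lut$R, lut$mua_grid, lut$musp_grid, mua, musp)
  structure(tibble(wavelength_nm = lut$metadata$wavelength_nm,
                   mod_freq_hz = lut$metadata$mod_freq_hz,
                   sds_mm = lut$metadata$sds_mm,
                   amplitude = Mod(R), phase_rad = -Arg(R)),
            class = c("fd_reflectance", class(tibble())))
}

bilinear_complex <- function(M, xg, yg, x, y) {
  if (x < min(xg) || x > max(xg) || y < min(yg) || y > max(yg))
    stop_bad_arg("query point outside LUT axes")
  ix <- max(1L, min(length(xg) - 1L, findInterval(x, xg)))
  iy <- max(1L, min(length(yg) - 1L, findInterval(y, yg)))
  fx <- (x - xg[ix]) / (xg[ix + 1] - xg[ix])
  fy <- (y - yg[iy]) / (yg[iy + 1] - yg[iy])
  (1 - fx) * (1 - fy) * M[ix, iy] + fx * (1 - fy) * M[ix + 1, iy] +
    (1 - fx) * fy * M[ix, iy + 1] + fx * fy * M[ix + 1, iy + 1]
}

#' DCS forward model backed by LUT batches
#'
#' Wraps a batch set so the field autocorrelation can be evaluated at
#' arbitrary bottom-layer `(mua, musp, BFi)`: `g1` is computed analytically
#' per coarse node from the recorded momentum transfer and linearly
#' interpolated between the two adjacent scattering nodes. Upper-layer BFi
#' values are fixed by the template medium.
#'
#' @param batches A [mc_lut_batches()] result.
#' @param wavelength DCS optical wavelength (nm) for the wavenumber.
#' @return A function `f(mua_bottom, musp_bottom, bfi_bottom, tau)`
#'   returning the g1 vector, with class `"dcs_forward"`.
#' @export
dcs_forward_from_batches <- function(batches, wavelength = 850) {
  medium <- batches$medium
  props <- medium_properties(medium, batches$wavelength)
  nl <- nrow(props)
  upper_mua <- props$mua[-nl]
  upper_bfi <- props$bfi[-nl]
  nodes <- batches$musp_coarse
  f <- function(mua_bottom, musp_bottom, bfi_bottom,
                tau = default_tau_grid()) {
    musp_bottom <- min(max(musp_bottom, min(nodes)), max(nodes))
    i <- max(1L, min(length(nodes) - 1L, findInterval(musp_bottom, nodes)))
    fx <- (musp_bottom - nodes[i]) / (nodes[i + 1] - nodes[i])
    g1_node <- function(b) {
      g1_from_batch(b, c(upper_mua, mua_bottom),
                    c(upper_bfi, bfi_bottom), tau = tau,
                    wavelength = wavelength)$g1
    }
    if (fx < 1e-12) g1_node(batches$batches[[i]])
    else if (fx > 1 - 1e-12) g1_node(batches$batches[[i + 1]])
    else (1 - fx) * g1_node(batches$batches[[i]]) +
         fx * g1_node(batches$batches[[i + 1]])
  }
  structure(f, class = c("dcs_forward", "function"), wavelength = wavelength)
}

#' Build a DCS LUT
#'
#' Tabulates normalized field-autocorrelation curves over the dense
#' bottom-layer scattering axis and the log-spaced BFi axis at a fixed
#' bottom-layer absorption. `g1^2` is stored so the instrument coherence
#' factor beta can be applied at query time via the Siegert relation.
#'
#' @inheritParams mc_lut_batches
#' @param mua Bottom-layer absorption (mm^-1) baked into the curves.
#' @param wavelength DCS optical wavelength (nm).
#' @param tau Delay grid (s).
#' @param batches Optional precomputed [mc_lut_batches()].
#' @return A `"dcs_lut"`: array `g1sq` (`musp_dense x bfi x tau`), axes and
#'   metadata.
#' @export
build_dcs_lut <- function(medium, axes, sim, mua, wavelength = 850,
                          tau = default_tau_grid(), n_repeats = 10,
                          batches = NULL) {
  if (is.null(batches))
    batches <- mc_lut_batches(medium, axes, sim, 830, n_repeats)
  fwd <- dcs_forward_from_batches(batches, wavelength)
  nodes <- batches$musp_coarse
  nb <- length(axes$bfi_grid)
  coarse <- array(NA_real_, c(length(nodes), nb, length(tau)))
  for (i in seq_along(nodes)) {
    b <- batches$batches[[i]]
    props <- medium_properties(batches$medium, batches$wavelength)
    nl <- nrow(props)
    k0 <- 2 * pi * b$n_per_layer / (wavelength * 1e-6)
    w <- absorption_weights(b, c(props$mua[-nl], mua))
    rate_upper <- drop(b$Y[, -nl, drop = FALSE] %*%
                         (2 * k0[-nl]^2 * props$bfi[-nl]))
    Yb <- b$Y[, nl]
    for (j in seq_len(nb)) {
      rate <- rate_upper + 2 * k0[nl]^2 * axes$bfi_grid[j] * Yb
      G1 <- vapply(tau, function(tt) sum(w * exp(-rate * tt)), numeric(1))
      coarse[i, j, ] <- G1 / sum(w)
    }
  }
  dense <- apply(coarse, c(2, 3), function(v)
    approx(nodes, v, xout = axes$musp_dense_dcs)$y)
  # apply() puts the interpolated axis first: [musp_dense x bfi x tau]
  meta <- list(
    wavelength_nm = wavelength, mua = mua, sds_mm = sim$sds,
    half_width_mm = sim$detector_half_width, seed = sim$seed,
    n_photons = sim$n_photons, n_repeats = batches$n_repeats,
    layers = medium$layer,
    medium_hash = object_md5(medium_properties(medium, batches$wavelength))
  )
  structure(list(g1sq = dense^2, musp_grid = axes$musp_dense_dcs,
                 bfi_grid = axes$bfi_grid, tau_s = tau, metadata = meta),
            class = "dcs_lut")
}

#' @export
print.dcs_lut <- function(x, ...) {
  cat(sprintf("<dcs_lut> %d musp x %d bfi x %d tau, %s nm, mua %.3g mm^-1\n",
              dim(x$g1sq)[1], dim(x$g1sq)[2], dim(x$g1sq)[3],
              x$metadata$wavelength_nm, x$metadata$mua))
  invisible(x)
}

#' Query a DCS LUT
#'
#' Returns the g2 curve at the nearest dense scattering node, interpolating
#' `g1^2` linearly in log-BFi, with the Siegert relation applied.
#'
#' @param lut A `"dcs_lut"`.
#' @param musp,bfi Bottom-layer query values.
#' @param beta Coherence factor.
#' @return A `"g2_curve"` tibble.
#' @export
lut_query_dcs <- function(lut, musp, bfi, beta) {
  g1sq <- dcs_g1sq_at(lut, musp, bfi)
  structure(tibble(tau_s = lut$tau_s, g2 = 1 + beta * g1sq),
            beta = beta, class = c("g2_curve", class(tibble())))
}

dcs_g1sq_at <- function(lut, musp, bfi) {
  im <- which.min(abs(lut$musp_grid - musp))
  bg <- lut$bfi_grid
  bfi <- min(max(bfi, bg[1]), bg[length(bg)])
  j <- max(1L, min(length(bg) - 1L, findInterval(bfi, bg)))
  fj <- (log(bfi) - log(bg[j])) / (log(bg[j + 1]) - log(bg[j]))
  (1 - fj) * lut$g1sq[im, j, ] + fj * lut$g1sq[im, j + 1, ]
}

#' Persist a LUT to a JSON file
#'
#' Full-precision (17 significant digits) version-stamped serialization;
#' arrays round-trip bit-identically and the payload carries an md5
#' checksum so a corrupted or hand-edited file is rejected on load.
#'
#' @param lut A `"fd_lut"` or `"dcs_lut"`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `load_lut()` returns the LUT.
#' @export
save_lut <- function(lut, path) {
  kind <- class(lut)[1]
  payload <- list(schema = "mldos_lut", version = 1L, kind = kind,
                  metadata = lut$metadata)
  if (kind == "fd_lut") {
    payload$mua_grid <- lut$mua_grid
    payload$musp_grid <- lut$musp_grid
    payload$R_re <- Re(lut$R)
    payload$R_im <- Im(lut$R)
    payload$payload_md5 <- object_md5(payload[c("R_re", "R_im")])
  } else if (kind == "dcs_lut") {
    payload$musp_grid <- lut$musp_grid
    payload$bfi_grid <- lut$bfi_grid
    payload$tau_s <- lut$tau_s
    payload$dim <- dim(lut$g1sq)
    payload$g1sq <- as.vector(lut$g1sq)
    payload$payload_md5 <- object_md5(payload["g1sq"])
  } else stop_bad_arg("not a LUT object")
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_lut
#' @export
load_lut <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "mldos_lut") || is.null(p$version))
    abort("not an mldos LUT file", class = "mldos_schema_error")
  if (p$version != 1L)
    abort(sprintf("unsupported LUT schema version %s", p$version),
          class = "mldos_schema_error")
  if (identical(p$kind, "fd_lut")) {
    if (!identical(object_md5(p[c("R_re", "R_im")]), p$payload_md5))
      abort("LUT payload does not match its checksum",
            class = "mldos_provenance_error")
    R <- matrix(complex(real = p$R_re, imaginary = p$R_im),
                nrow = length(p$mua_grid))
    structure(list(R = R, mua_grid = p$mua_grid, musp_grid = p$musp_grid,
                   metadata = as.list(p$metadata)), class = "fd_lut")
  } else if (identical(p$kind, "dcs_lut")) {
    if (!identical(object_md5(p["g1sq"]), p$payload_md5))
      abort("LUT payload does not match its checksum",
            class = "mldos_provenance_error")
    structure(list(g1sq = array(p$g1sq, p$dim), musp_grid = p$musp_grid,
                   bfi_grid = p$bfi_grid, tau_s = p$tau_s,
                   metadata = as.list(p$metadata)), class = "dcs_lut")
  } else abort("unknown LUT kind", class = "mldos_schema_error")
}
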