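#' Invert calibrated FD-NIRS measurements against an FD LUT
#'
#' Dense grid search minimizing
#' `chi^2 = (d ln A / sigma_A)^2 + (d phase / sigma_phase)^2`
#' per wavelength. Ties are broken toward the smallest absorption, then the
#' smallest scattering; a minimum on an axis edge sets a boundary flag
#' rather than failing.
#'
#' @param measurement An `fd_reflectance` tibble (one row per wavelength /
#'   modulation frequency), amplitudes on the LUT's per-launched-photon
#'   scale or related to it by `calibration`.
#' @param lut A `"fd_lut"`, or a list of them named by wavelength in nm.
#' @param calibration Complex factor multiplying the measured complex
#'   reflectance into model space (default 1, i.e. already calibrated).
#' @param sigma_amp,sigma_phase Objective weights for log-amplitude and
#'   phase residuals (default unweighted).
#' @return A tibble with class `"fd_fit"`: one row per measurement row with
#'   `mua`, `musp`, `objective`, boundary flags and `model_tag` metadata.
#' @export
invert_fd <- function(measurement, lut, calibration = 1 + 0i,
                      sigma_amp = 1, sigma_phase = 1) {
  luts <- if (inherits(lut, "fd_lut")) {
    setNames(list(lut), as.character(lut$metadata$wavelength_nm))
  } else lut
  rows <- lapply(seq_len(nrow(measurement)), function(i) {
    m <- measurement[i, ]
    l <- luts[[as.character(m$wavelength_nm)]]
    if (is.null(l))
      stop_bad_arg(sprintf("no LUT supplied for wavelength %s nm",
                           m$wavelength_nm))
    z <- m$amplitude * exp(-1i * m$phase_rad) * calibration
    fit_fd_single(Mod(z), -Arg(z), l, sigma_amp, sigma_phase) |>
      dplyr::mutate(wavelength_nm = m$wavelength_nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model_tag") <- "multi_layer"
  class(out) <- c("fd_fit", class(tibble()))
  out
}

fit_fd_single <- function(amp, phase, lut, sigma_amp, sigma_phase) {
  la <- log(amp)
  LA <- log(Mod(lut$R))
  PH <- -Arg(lut$R)
  obj <- ((LA - la) / sigma_amp)^2 + ((PH - phase) / sigma_phase)^2
  best <- which(obj == min(obj), arr.ind = TRUE)
  if (nrow(best) > 1) best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  i <- best[1, 1]; j <- best[1, 2]
  tibble(
    mua = lut$mua_grid[i], musp = lut$musp_grid[j],
    objective = obj[i, j],
    boundary_mua = i == 1L || i == length(lut$mua_grid),
    boundary_musp = j == 1L || j == length(lut$musp_grid)
  )
}

#' Invert a measured intensity autocorrelation for the blood flow index
#'
#' Least squares over the BFi axis (continuous refinement between grid
#' nodes) minimizing `sum_tau (g2_model - g2_meas)^2` inside the default
#' delay window where the measured correlation is above the noise floor
#' (`g2 - 1 > 0.01 beta`). The coherence factor beta may be fixed or fitted
#' (linear least squares of `g2 - 1` on `g1^2`).
#'
#' @param g2_measured A `"g2_curve"` tibble (columns `tau_s`, `g2`).
#' @param model Either a `"dcs_lut"` or a `"dcs_forward"` function from
#'   [dcs_forward_from_batches()].
#' @param mua,musp Bottom-layer optical properties at the DCS wavelength,
#'   typically from the FD fit at the matched wavelength. For a
#'   `"dcs_lut"` model, `mua` is already baked in and only `musp` is used.
#' @param beta Coherence factor; numeric to fix, `NULL` to fit.
#' @param tau_window Optional logical vector / delay filter overriding the
#'   noise-floor default.
#' @return A one-row tibble with class `"dcs_fit"`: `bfi`, `beta`,
#'   `residual_rms`, `boundary_bfi`, `model_tag`.
#' @export
invert_dcs <- function(g2_measured, model, mua = NULL, musp = NULL,
                       beta = 0.45, tau_window = NULL) {
  tau <- g2_measured$tau_s
  g2m <- g2_measured$g2
  if (any(g2m < 1 - 0.1))
    abort("non-physical g2 values well below 1", class = "mldos_data_error")
  beta_fixed <- !is.null(beta)
  beta0 <- if (beta_fixed) beta else max(g2m[1] - 1, 0.1)
  win <- tau_window %||% (g2m - 1 > 0.01 * beta0)
  if (sum(win) < 3)
    abort("too few delays above the noise floor", class = "mldos_data_error")

  if (inherits(model, "dcs_lut")) {
    if (is.null(musp)) stop_bad_arg("`musp` required for a dcs_lut model")
    bfi_grid <- model$bfi_grid
    if (!isTRUE(all.equal(tau, model$tau_s)))
      stop_bad_arg("measurement tau grid must match the LUT tau grid")
    g1sq_fun <- function(b) dcs_g1sq_at(model, musp, b)
  } else {
    if (is.null(mua) || is.null(musp))
      stop_bad_arg("`mua` and `musp` required for a forward model")
    bfi_grid <- exp(seq(log(0.1e-6), log(40e-6), length.out = 121))
    g1sq_fun <- function(b) model(mua, musp, b, tau)^2
  }

  sse_beta <- function(b) {
    g1sq <- g1sq_fun(b)[win]
    bb <- if (beta_fixed) beta else
      min(1, max(0, sum((g2m[win] - 1) * g1sq) / sum(g1sq^2)))
    c(sum((1 + bb * g1sq - g2m[win])^2), bb)
  }
  vals <- vapply(bfi_grid, function(b) sse_beta(b)[1], numeric(1))
  k <- which.min(vals)
  lo <- bfi_grid[max(1, k - 1)]; hi <- bfi_grid[min(length(bfi_grid), k + 1)]
  opt <- optimize(function(lb) sse_beta(exp(lb))[1], c(log(lo), log(hi)))
  bfi_hat <- exp(opt$minimum)
  res <- sse_beta(bfi_hat)
  out <- tibble(
    bfi = bfi_hat, beta = res[2],
    residual_rms = sqrt(res[1] / sum(win)),
    boundary_bfi = k == 1L || k == length(bfi_grid)
  )
  class(out) <- c("dcs_fit", class(tibble()))
  out
}

#' Fit a measurement time series frame by frame
#'
#' Applies [invert_fd()] (per wavelength) and optionally [invert_dcs()] to
#' every frame independently. Frames are independent fits: permutation of
#' frame order does not change results. Per-frame failures are recorded in
#' the `ok`/`note` columns rather than aborting the series.
#'
#' @param fd_frames Tibble of FD measurements with columns `frame`,
#'   `time_s`, `wavelength_nm`, `mod_freq_hz`, `amplitude`, `phase_rad`.
#' @param fd_luts List of `"fd_lut"` named by wavelength.
#' @param dcs_frames Optional tibble with columns `frame`, `time_s`,
#'   `tau_s`, `g2`.
#' @param dcs_model Optional `"dcs_lut"` or `"dcs_forward"`; required with
#'   `dcs_frames`.
#' @param dcs_wavelength_ref Wavelength (nm) whose FD fit supplies
#'   `mua`/`musp` to the DCS inversion.
#' @param beta Coherence factor passed to [invert_dcs()].
#' @param calibration Complex calibration factor for [invert_fd()].
#' @return Tibble, one row per frame: recovered `mua_<wl>`, `musp_<wl>`,
#'   `bfi`, `beta`, flags.
#' @export
fit_timeseries <- function(fd_frames, fd_luts, dcs_frames = NULL,
                           dcs_model = NULL, dcs_wavelength_ref = 830,
                           beta = 0.35, calibration = 1 + 0i) {
  frames <- sort(unique(fd_frames$frame))
  purrr::map_dfr(frames, function(fr) {
    fdm <- dplyr::filter(fd_frames, .data$frame == fr)
    row <- tibble(frame = fr, time_s = fdm$time_s[1], ok = TRUE,
                  note = NA_character_)
    fit <- tryCatch(
      invert_fd(fdm, fd_luts, calibration = calibration),
      error = function(e) NULL)
    if (is.null(fit)) {
      row$ok <- FALSE; row$note <- "fd fit failed"
      return(row)
    }
    for (i in seq_len(nrow(fit))) {
      wl <- fit$wavelength_nm[i]
      row[[paste0("mua_", wl)]] <- fit$mua[i]
      row[[paste0("musp_", wl)]] <- fit$musp[i]
      row[[paste0("boundary_", wl)]] <-
        fit$boundary_mua[i] || fit$boundary_musp[i]
    }
    if (!is.null(dcs_frames)) {
      dm <- dplyr::filter(dcs_frames, .data$frame == fr)
      ref <- dplyr::filter(fit, .data$wavelength_nm == dcs_wavelength_ref)
      dfit <- tryCatch(
        invert_dcs(dm, dcs_model, mua = ref$mua[1], musp = ref$musp[1],
                   beta = beta),
        error = function(e) NULL)
      if (is.null(dfit)) {
        row$ok <- FALSE; row$note <- "dcs fit failed"
      } else {
        row$bfi <- dfit$bfi; row$beta <- dfit$beta
        row$boundary_bfi <- dfit$boundary_bfi
      }
    }
    row
  })
}

#' Phantom-reference complex calibration factor
#'
#' Ratio of the model-predicted to the measured complex reflectance on a
#' reference medium of known optical properties; multiplying raw
#' measurements by this factor maps them into LUT model space.
#'
#' @param measured An `fd_reflectance` row measured on the reference.
#' @param predicted An `fd_reflectance` row predicted for the reference
#'   (e.g. via [lut_query_fd()] on a homogeneous LUT).
#' @return Complex scalar calibration factor.
#' @export
calibration_factor <- function(measured, predicted) {
  zm <- measured$amplitude * exp(-1i * measured$phase_rad)
  zp <- predicted$amplitude * exp(-1i * predicted$phase_rad)
  zp / zm
}
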