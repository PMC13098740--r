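#' Upper-layer perturbation magnitudes
#'
#' The eight one-at-a-time perturbations of the assumed skin/adipose model
#' parameters, with magnitudes set from the reported population variability
#' of each parameter (approximate standard deviation over mean, in
#' percent; adipose thickness fixed at 10%).
#'
#' @return Tibble with columns `parameter`, `magnitude_pct`.
#' @export
perturbation_table <- function() {
  tibble(
    parameter = c("skin_thickness", "skin_mua", "skin_musp",
                  "adipose_thickness", "adipose_mua", "adipose_musp",
                  "skin_bfi", "adipose_bfi"),
    magnitude_pct = c(10, 75, 25, 10, 30, 30, 30, 25)
  )
}

perturbation_affects_transport <- function(parameter) {
  grepl("thickness|musp", parameter)
}

#' Apply a relative perturbation to an upper-layer model parameter
#'
#' @param medium A [layered_medium()] whose first two layers are skin and
#'   adipose.
#' @param parameter One of the [perturbation_table()] parameters.
#' @param magnitude_pct Relative perturbation in percent.
#' @param direction `+1` or `-1` for one-sided perturbations.
#' @return The perturbed [layered_medium()].
#' @export
perturb_medium <- function(medium, parameter, magnitude_pct,
                           direction = 1) {
  if (!parameter %in% perturbation_table()$parameter)
    stop_bad_arg(sprintf("unknown perturbation '%s'", parameter))
  f <- 1 + direction * magnitude_pct / 100
  row <- if (grepl("^skin", parameter)) 1L else 2L
  field <- sub("^(skin|adipose)_", "", parameter)
  if (field == "thickness") {
    medium$thickness_mm[row] <- medium$thickness_mm[row] * f
  } else if (field == "mua") {
    medium$mua[[row]] <- medium$mua[[row]] * f
  } else if (field == "musp") {
    medium$musp[[row]] <- medium$musp[[row]] * f
  } else if (field == "bfi") {
    medium$bfi[row] <- medium$bfi[row] * f
  }
  medium
}

#' One-at-a-time sensitivity of recovered bottom-layer properties
#'
#' Forward-models the perturbed medium, inverts with the UNperturbed
#' multi-layer LUTs, and reports
#' `Sensitivity = ((recovered - truth)/truth * 100%) / perturbation%`
#' for recovered absorption and reduced scattering per wavelength and
#' (when a DCS model is given) the blood flow index. The base medium's
#' bottom layer supplies the ground truth.
#'
#' Perturbations of upper-layer absorption or BFi do not alter photon
#' paths under white-absorption transport, so a precomputed unperturbed
#' forward batch (`forward_batches`) can be reweighted instead of
#' re-simulated; geometry and scattering perturbations always trigger a
#' fresh simulation per seed.
#'
#' @param base Unperturbed [layered_medium()] (e.g. 1 mm-adipose tissue
#'   model); bottom layer = ground truth.
#' @param perturbation A row of [perturbation_table()] or a parameter name.
#' @param sim A [sim_config()] (per-replicate photon budget).
#' @param fd_luts Named list of unperturbed `"fd_lut"`s keyed by wavelength.
#' @param dcs_model Optional unperturbed `"dcs_lut"` or `"dcs_forward"`.
#' @param beta Coherence factor used for the synthetic g2 and its fit.
#' @param wavelengths FD output wavelengths to report (default 830 nm).
#' @param dcs_wavelength DCS optical wavelength (nm).
#' @param seeds Integer vector of replicate indices; each replicate uses a
#'   seed derived from `sim$seed` and the replicate index.
#' @param forward_batches Optional list over replicates of named (by
#'   wavelength) unperturbed forward `photon_batch`es at the truth bottom
#'   scattering, reused for non-transport perturbations.
#' @param direction Perturbation sign.
#' @return Tibble with class `"sensitivity_result"`: one row per
#'   (replicate x output).
#' @export
run_sensitivity <- function(base, perturbation, sim, fd_luts,
                            dcs_model = NULL, beta = 0.35,
                            wavelengths = c(830), dcs_wavelength = 850,
                            seeds = 1:3, forward_batches = NULL,
                            direction = 1) {
  if (is.character(perturbation)) {
    pt <- perturbation_table()
    perturbation <- pt[pt$parameter == perturbation, ]
  }
  par <- perturbation$parameter
  pct <- perturbation$magnitude_pct
  med_p <- perturb_medium(base, par, pct, direction)
  needs_mc <- perturbation_affects_transport(par)
  nlay <- nrow(base)
  truth <- medium_properties(base, wavelengths[1])[nlay, ]

  rows <- purrr::map_dfr(seq_along(seeds), function(si) {
    out <- tibble()
    batches <- list()
    for (wl in wavelengths) {
      b <- if (!needs_mc && !is.null(forward_batches))
        forward_batches[[si]][[as.character(wl)]]
      else NULL
      if (is.null(b)) {
        sim_s <- sim
        sim_s$seed <- derive_seed(sim$seed, match(par, perturbation_table()$parameter),
                                  si, wl)
        b <- run_layered_mc(med_p, sim_s, wl)
      }
      batches[[as.character(wl)]] <- b
      props_p <- medium_properties(med_p, wl)
      lutw <- fd_luts[[as.character(wl)]]
      z <- fd_from_batch(b, props_p$mua, lutw$metadata$mod_freq_hz) /
        b$n_launched
      meas <- tibble(wavelength_nm = wl,
                     mod_freq_hz = lutw$metadata$mod_freq_hz,
                     amplitude = Mod(z), phase_rad = -Arg(z))
      fit <- invert_fd(meas, lutw)
      tw <- medium_properties(base, wl)[nlay, ]
      out <- dplyr::bind_rows(out,
        tibble(parameter = par, magnitude_pct = pct, replicate = si,
               output = c("mua", "musp"), wavelength_nm = wl,
               truth = c(tw$mua, tw$musp),
               recovered = c(fit$mua, fit$musp),
               boundary = c(fit$boundary_mua, fit$boundary_musp)))
    }
    if (!is.null(dcs_model)) {
      wl_ref <- as.character(wavelengths[1])
      b <- batches[[wl_ref]]
      props_p <- medium_properties(med_p, as.numeric(wl_ref))
      tau <- if (inherits(dcs_model, "dcs_lut")) dcs_model$tau_s
             else default_tau_grid()
      g1 <- g1_from_batch(b, props_p$mua, props_p$bfi, tau = tau,
                          wavelength = dcs_wavelength)
      g2 <- siegert(g1, beta)
      recw <- out[out$output %in% c("mua", "musp") &
                    out$wavelength_nm == as.numeric(wl_ref) &
                    out$replicate == si, ]
      dfit <- invert_dcs(g2, dcs_model,
                         mua = recw$recovered[recw$output == "mua"],
                         musp = recw$recovered[recw$output == "musp"],
                         beta = beta)
      out <- dplyr::bind_rows(out,
        tibble(parameter = par, magnitude_pct = pct, replicate = si,
               output = "bfi", wavelength_nm = dcs_wavelength,
               truth = truth$bfi, recovered = dfit$bfi,
               boundary = dfit$boundary_bfi))
    }
    out
  })
  rows$sensitivity <- ((rows$recovered - rows$truth) / rows$truth * 100) / pct
  class(rows) <- c("sensitivity_result", class(tibble()))
  rows
}

#' Aggregate sensitivity replicates into a report
#'
#' @param results A `"sensitivity_result"` tibble (rows from one or more
#'   [run_sensitivity()] calls; may carry an extra `skin_tone` column).
#' @return Tibble keyed by (parameter, output, wavelength and skin tone if
#'   present) with replicate mean, standard error and count.
#' @export
sensitivity_report <- function(results) {
  if (nrow(results) == 0) return(tibble())
  keys <- intersect(c("parameter", "magnitude_pct", "output",
                      "wavelength_nm", "skin_tone"), names(results))
  dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(keys))),
    sensitivity_mean = mean(.data$sensitivity),
    sensitivity_se = sd(.data$sensitivity) /
      sqrt(max(1, dplyr::n() - 0)),
    n = dplyr::n(),
    any_boundary = any(.data$boundary),
    .groups = "drop")
}
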