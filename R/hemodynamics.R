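#' Bundled chromophore extinction / background absorption table
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin (base-10,
#' 1/(cm M)) and pure water / lipid absorption (mm^-1) at the FD-NIRS
#' wavelengths, compiled from standard literature tabulations. The table is
#' packaged as CSV so alternative compilations can be swapped in via the
#' `extinction` argument of [mua_to_chromophores()].
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return Tibble with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`,
#'   `mua_water`, `mua_lipid`.
#' @export
extinction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "extinction_coefficients.csv",
                                package = "mldos")
  as_tibble(read.csv(path, comment.char = "#"))
}

# mm^-1 per umol/L from a base-10 molar extinction in 1/(cm M):
# ln(10) converts to natural log, /10 cm->mm, *1e-6 M->uM
eps_to_mm_per_uM <- function(eps) log(10) * eps * 1e-7

#' Chromophore concentrations from absorption at two wavelengths
#'
#' Solves the 2x2 Beer-Lambert system for combined oxy- and
#' deoxy-hemoglobin-plus-myoglobin concentrations from muscle absorption at
#' 730 and 830 nm, after subtracting fixed water (62.5%) and lipid (20%)
#' background absorption:
#' `mua(lambda) - f_w mua_w - f_l mua_l = ln10 (eps_HbO2 oxy + eps_Hb deoxy)`.
#' Negative solutions are flagged, not silently clipped.
#'
#' @param mua_730,mua_830 Absorption coefficients (mm^-1); vectorized.
#' @param water_fraction,lipid_fraction Volume fractions of water and lipid
#'   assumed in the tissue.
#' @param extinction Extinction table, see [extinction_table()].
#' @return Tibble with `oxy_uM`, `deoxy_uM`, `total_uM` (umol/L) and a
#'   `nonphysical` flag for negative concentrations.
#' @export
mua_to_chromophores <- function(mua_730, mua_830, water_fraction = 0.625,
                                lipid_fraction = 0.20,
                                extinction = extinction_table()) {
  if (water_fraction < 0 || water_fraction > 1 ||
      lipid_fraction < 0 || lipid_fraction > 1)
    stop_bad_arg("fractions must be in [0, 1]")
  ext <- extinction[match(c(730, 830), extinction$wavelength_nm), ]
  if (any(is.na(ext$wavelength_nm)))
    stop_bad_arg("extinction table must cover 730 and 830 nm")
  E <- rbind(c(eps_to_mm_per_uM(ext$eps_hbo2[1]), eps_to_mm_per_uM(ext$eps_hb[1])),
             c(eps_to_mm_per_uM(ext$eps_hbo2[2]), eps_to_mm_per_uM(ext$eps_hb[2])))
  if (abs(det(E)) < 1e-12 * max(abs(E))^2)
    abort("extinction matrix is singular or ill-conditioned",
          class = "mldos_numeric_error")
  bg <- water_fraction * ext$mua_water + lipid_fraction * ext$mua_lipid
  rhs <- rbind(mua_730 - bg[1], mua_830 - bg[2])
  sol <- solve(E, rhs)
  tibble(oxy_uM = sol[1, ], deoxy_uM = sol[2, ],
         total_uM = sol[1, ] + sol[2, ],
         nonphysical = sol[1, ] < 0 | sol[2, ] < 0)
}

#' Forward-compose absorption from chromophore concentrations
#'
#' Inverse of [mua_to_chromophores()]; useful for synthetic data generation
#' and round-trip checks.
#'
#' @param oxy_uM,deoxy_uM Concentrations in umol/L; vectorized.
#' @inheritParams mua_to_chromophores
#' @return Tibble with `mua_730`, `mua_830` (mm^-1).
#' @export
chromophores_to_mua <- function(oxy_uM, deoxy_uM, water_fraction = 0.625,
                                lipid_fraction = 0.20,
                                extinction = extinction_table()) {
  ext <- extinction[match(c(730, 830), extinction$wavelength_nm), ]
  bg <- water_fraction * ext$mua_water + lipid_fraction * ext$mua_lipid
  tibble(
    mua_730 = bg[1] + eps_to_mm_per_uM(ext$eps_hbo2[1]) * oxy_uM +
      eps_to_mm_per_uM(ext$eps_hb[1]) * deoxy_uM,
    mua_830 = bg[2] + eps_to_mm_per_uM(ext$eps_hbo2[2]) * oxy_uM +
      eps_to_mm_per_uM(ext$eps_hb[2]) * deoxy_uM
  )
}

#' Tissue oxygen saturation
#'
#' `StO2 = 100 * oxy / total` in percent.
#'
#' @param oxy,total Oxygenated and total hemoglobin(+myoglobin), umol/L.
#' @return StO2 in percent.
#' @export
compute_sto2 <- function(oxy, total) {
  if (any(total <= 0))
    abort("total concentration must be > 0", class = "mldos_undefined_result")
  100 * oxy / total
}

#' Metabolic rate of oxygen
#'
#' `MRO2 = HGB x BFi x (SpO2 - StO2) / (venous ratio x mw Hb)` with the
#' blood hemoglobin concentration HGB converted to g/L and saturations as
#' fractions. Reported in mol mm^2 L^-1 s^-1 (the BFi carries the
#' perfusion units); MRO2 is linear in BFi and in the arterio-tissue
#' saturation gap and changes sign with it.
#'
#' @param bfi Blood flow index, mm^2/s.
#' @param sto2_pct Tissue saturation in percent (0-100).
#' @param hgb_g_dl Blood hemoglobin concentration, g/dL; defaults 16 (male)
#'   / 14 (female) via `sex`.
#' @param sex `"male"` or `"female"`, used only when `hgb_g_dl` is `NULL`.
#' @param spo2 Peripheral arterial saturation as a fraction.
#' @param venous_ratio Venous blood volume fraction.
#' @param mw_hb Molecular weight of hemoglobin, g/mol.
#' @return MRO2 values (mol mm^2 L^-1 s^-1); vectorized over `bfi` and
#'   `sto2_pct`.
#' @export
compute_mro2 <- function(bfi, sto2_pct, hgb_g_dl = NULL,
                         sex = c("male", "female"), spo2 = 0.98,
                         venous_ratio = 0.75, mw_hb = 64500) {
  sex <- match.arg(sex)
  hgb_g_dl <- hgb_g_dl %||% if (sex == "male") 16 else 14
  if (hgb_g_dl <= 0 || spo2 <= 0 || spo2 > 1 || venous_ratio <= 0 ||
      venous_ratio > 1 || mw_hb <= 0)
    stop_bad_arg("invalid MRO2 parameters")
  if (any(sto2_pct < 0 | sto2_pct > 100, na.rm = TRUE))
    stop_bad_arg("`sto2_pct` must be within [0, 100]")
  (hgb_g_dl * 10 / mw_hb) * bfi * (spo2 - sto2_pct / 100) / venous_ratio
}

#' Hemodynamic parameters from a fitted time series
#'
#' Convenience wrapper chaining [mua_to_chromophores()], [compute_sto2()]
#' and [compute_mro2()] over the per-frame fits of [fit_timeseries()].
#'
#' @param fits Tibble from [fit_timeseries()] with `mua_730`, `mua_830`
#'   and (optionally) `bfi` columns.
#' @inheritParams compute_mro2
#' @inheritParams mua_to_chromophores
#' @return `fits` with `oxy_uM`, `deoxy_uM`, `total_uM`, `sto2_pct` and
#'   (when `bfi` is present) `mro2` columns appended.
#' @export
hemodynamics_from_fits <- function(fits, sex = c("male", "female"),
                                   hgb_g_dl = NULL, spo2 = 0.98,
                                   venous_ratio = 0.75,
                                   water_fraction = 0.625,
                                   lipid_fraction = 0.20) {
  sex <- match.arg(sex)
  ch <- mua_to_chromophores(fits$mua_730, fits$mua_830,
                            water_fraction, lipid_fraction)
  out <- dplyr::bind_cols(fits, ch)
  out$sto2_pct <- 100 * out$oxy_uM / out$total_uM
  if ("bfi" %in% names(out)) {
    st <- pmin(pmax(out$sto2_pct, 0), 100)
    out$mro2 <- compute_mro2(out$bfi, st, hgb_g_dl = hgb_g_dl, sex = sex,
                             spo2 = spo2, venous_ratio = venous_ratio)
  }
  out
}
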