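#' Layered optical media
#'
#' A layered medium is an ordered top-to-bottom stack of optical layers over
#' a semi-infinite bottom layer. Each layer carries a thickness (mm), maps of
#' absorption and reduced scattering coefficients keyed by wavelength
#' (mm^-1), the scattering anisotropy g, refractive index n, and a blood
#' flow index BFi (mm^2/s, the effective Brownian diffusion coefficient of
#' moving scatterers). Media are tibbles with one row per layer plus
#' attributes for the ambient refractive index and the wavelength registry,
#' so they print and manipulate like ordinary data frames.
#'
#' @param name Layer label.
#' @param thickness_mm Layer thickness in mm. Use `Inf` for the
#'   semi-infinite bottom layer.
#' @param mua Named numeric vector of absorption coefficients (mm^-1) keyed
#'   by wavelength in nm, e.g. `c("730" = 0.019, "830" = 0.006)`.
#' @param musp Named numeric vector of reduced scattering coefficients
#'   (mm^-1), keyed like `mua`.
#' @param g Scattering anisotropy, in `[0, 1)`.
#' @param n Refractive index, >= 1.
#' @param bfi Blood flow index in mm^2/s, >= 0.
#' @return A one-row tibble describing the layer.
#' @export
optical_layer <- function(name, thickness_mm, mua, musp, g, n, bfi = 0) {
  if (!is_scalar_number(thickness_mm) && !identical(thickness_mm, Inf))
    stop_bad_arg("`thickness_mm` must be a single positive number or Inf")
  if (thickness_mm < 0) stop_bad_arg("`thickness_mm` must be >= 0")
  if (is.null(names(mua)) || is.null(names(musp)))
    stop_bad_arg("`mua` and `musp` must be named by wavelength (nm)")
  if (!setequal(names(mua), names(musp)))
    stop_bad_arg("`mua` and `musp` must cover the same wavelengths")
  if (any(mua < 0)) stop_bad_arg("`mua` must be >= 0")
  if (any(musp < 0)) stop_bad_arg("`musp` must be >= 0")
  if (g < 0 || g >= 1) stop_bad_arg("`g` must be in [0, 1)")
  if (n < 1) stop_bad_arg("`n` must be >= 1")
  if (bfi < 0) stop_bad_arg("`bfi` must be >= 0")
  tibble(
    layer = name, thickness_mm = thickness_mm,
    mua = list(mua[order(as.numeric(names(mua)))]),
    musp = list(musp[order(as.numeric(names(musp)))]),
    g = g, n = n, bfi = bfi
  )
}

#' @param layers A tibble of layers built with [optical_layer()], ordered
#'   top to bottom; only the last layer may be semi-infinite.
#' @param ambient_n Refractive index of the medium above the top surface
#'   (1.0 = air).
#' @rdname optical_layer
#' @export
layered_medium <- function(layers, ambient_n = 1.0) {
  if (nrow(layers) < 1) stop_bad_arg("a medium needs at least one layer")
  fin <- is.finite(layers$thickness_mm)
  if (any(!fin[-nrow(layers)]))
    stop_bad_arg("only the bottom layer may be semi-infinite")
  wl <- names(layers$mua[[1]])
  for (i in seq_len(nrow(layers))) {
    if (!setequal(names(layers$mua[[i]]), wl))
      stop_bad_arg("all layers must share the same wavelength set")
  }
  structure(layers,
            ambient_n = ambient_n,
            wavelengths_nm = as.numeric(wl),
            class = c("layered_medium", class(tibble())))
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> %d layers, ambient n = %.3g, wavelengths: %s nm\n",
              nrow(x), attr(x, "ambient_n"),
              paste(attr(x, "wavelengths_nm"), collapse = ", ")))
  NextMethod()
}

#' Extract per-layer scalar properties at one wavelength
#'
#' @param medium A [layered_medium()].
#' @param wavelength Wavelength in nm; must be in the medium's registry. For
#'   the DCS wavelength (850 nm) the nearest tabulated wavelength's
#'   properties are used with a note, matching the convention of tabulating
#'   optical properties at the FD-NIRS wavelengths only.
#' @return Tibble with columns layer, thickness_mm, mua, musp, g, n, bfi.
#' @export
medium_properties <- function(medium, wavelength) {
  wl <- attr(medium, "wavelengths_nm")
  key <- as.character(wavelength)
  if (!wavelength %in% wl) {
    near <- wl[which.min(abs(wl - wavelength))]
    key <- as.character(near)
  }
  tibble(
    layer = medium$layer,
    thickness_mm = medium$thickness_mm,
    mua = vapply(medium$mua, function(m) unname(m[key]), numeric(1)),
    musp = vapply(medium$musp, function(m) unname(m[key]), numeric(1)),
    g = medium$g, n = medium$n, bfi = medium$bfi
  )
}

#' Classify skin tone from the individual typology angle
#'
#' The individual typology angle (ITA, degrees) is a colorimetric skin-tone
#' measure. ITA above 41 degrees classifies as light, below 10 degrees as
#' dark, and the closed interval between (including the boundary values 10
#' and 41) as medium.
#'
#' @param ita_deg Numeric vector of ITA values in degrees.
#' @return Character vector in `c("light", "medium", "dark")`.
#' @export
classify_ita <- function(ita_deg) {
  if (!is.numeric(ita_deg) || any(!is.finite(ita_deg)))
    stop_bad_arg("`ita_deg` must be finite numeric")
  ifelse(ita_deg > 41, "light", ifelse(ita_deg < 10, "dark", "medium"))
}

# Skin rows: light/medium/dark share musp, g, n, BFi; only mua varies with
# pigmentation. Values per wavelength (730 / 830 nm). BFi of the upper
# subcutaneous layers (skin + adipose) is 0.6e-6 mm^2/s.
.tissue_skin <- list(
  light  = list(mua = c("730" = 0.019, "830" = 0.006)),
  medium = list(mua = c("730" = 0.051, "830" = 0.017)),
  dark   = list(mua = c("730" = 0.149, "830" = 0.044))
)
.tissue_skin_musp <- c("730" = 1.34, "830" = 1.17)
.tissue_adipose <- list(
  mua = c("730" = 0.010, "830" = 0.010),
  musp = c("730" = 1.19, "830" = 1.09)
)
.upper_bfi <- 0.6e-6

#' Default muscle layer for tissue media
#'
#' The tabulated muscle ranges span mua 0.01-0.2 mm^-1, musp 0.1-1.0 mm^-1
#' and BFi 0.1-40 x 10^-6 mm^2/s; this constructor fills in a representative
#' resting skeletal-muscle point within those ranges (overridable per
#' argument) with the fixed g = 0.9 and n = 1.38.
#'
#' @param mua,musp Named per-wavelength coefficient vectors (mm^-1).
#' @param bfi Blood flow index (mm^2/s).
#' @return A one-row layer tibble.
#' @export
muscle_layer <- function(mua = c("730" = 0.030, "830" = 0.025),
                         musp = c("730" = 0.75, "830" = 0.70),
                         bfi = 2e-6) {
  optical_layer("muscle", Inf, mua = mua, musp = musp,
                g = 0.9, n = 1.38, bfi = bfi)
}

#' Three-layer tissue medium for a given skin tone and adipose thickness
#'
#' Builds the skin / adipose / muscle stack used by the multi-layer inverse
#' models: a 1 mm skin layer whose absorption depends on skin tone, an
#' adipose layer of the requested thickness, and a semi-infinite muscle
#' layer. Upper-layer (skin and adipose) blood flow index is fixed at
#' 0.6e-6 mm^2/s.
#'
#' @param skin_tone `"light"`, `"medium"` or `"dark"`, or a numeric ITA in
#'   degrees (classified via [classify_ita()]).
#' @param adipose_thickness_mm Adipose thickness in mm; values outside
#'   `[0, 6]` emit a warning. A zero thickness drops the layer's physical
#'   extent (the layer row is kept for bookkeeping).
#' @param muscle Bottom layer, from [muscle_layer()].
#' @param ambient_n Refractive index above the skin (default air).
#' @return A [layered_medium()].
#' @export
tissue_medium <- function(skin_tone, adipose_thickness_mm,
                          muscle = muscle_layer(), ambient_n = 1.0) {
  if (is.numeric(skin_tone)) skin_tone <- classify_ita(skin_tone)
  if (!skin_tone %in% names(.tissue_skin))
    stop_bad_arg(sprintf("unknown skin tone '%s'", skin_tone))
  if (adipose_thickness_mm < 0)
    stop_bad_arg("`adipose_thickness_mm` must be >= 0")
  if (adipose_thickness_mm > 6)
    warn("adipose thickness beyond the 0-6 mm preset range")
  skin <- optical_layer(paste0(skin_tone, "_skin"), 1,
                        mua = .tissue_skin[[skin_tone]]$mua,
                        musp = .tissue_skin_musp,
                        g = 0.9, n = 1.40, bfi = .upper_bfi)
  adipose <- optical_layer("adipose", adipose_thickness_mm,
                           mua = .tissue_adipose$mua,
                           musp = .tissue_adipose$musp,
                           g = 0.9, n = 1.44, bfi = .upper_bfi)
  layered_medium(dplyr::bind_rows(skin, adipose, muscle),
                 ambient_n = ambient_n)
}

.phantom_skin <- list(
  light  = list(mua = c("730" = 0.010, "830" = 0.007),
                musp = c("730" = 1.62, "830" = 1.27)),
  medium = list(mua = c("730" = 0.059, "830" = 0.040),
                musp = c("730" = 1.36, "830" = 1.09)),
  dark   = list(mua = c("730" = 0.106, "830" = 0.073),
                musp = c("730" = 0.78, "830" = 0.60))
)
.phantom_adipose <- list(mua = c("730" = 0.008, "830" = 0.006),
                         musp = c("730" = 1.49, "830" = 1.27))
.phantom_bottom <- list(
  silicone_muscle = list(mua = c("730" = 0.041, "830" = 0.072),
                         musp = c("730" = 0.42, "830" = 0.38),
                         g = 0.9, n = 1.40, bfi = 0),
  intralipid_muscle = list(mua = c("730" = 0.007, "830" = 0.006),
                           musp = c("730" = 0.40, "830" = 0.34),
                           g = 0.61, n = 1.37, bfi = 1.05e-6)
)

#' Stackable phantom medium
#'
#' Builds the silicone phantom stack used for validation: a 1 mm skin-tone
#' phantom, an adipose phantom of the requested thickness (physically
#' composable from 1, 2 and 4 mm stack elements), and either a solid
#' silicone muscle bottom (static, BFi = 0) or an intralipid liquid muscle
#' bottom (Brownian, BFi = 1.05e-6 mm^2/s).
#'
#' @param skin_tone `"light"`, `"medium"` or `"dark"` (phantom mimics).
#' @param adipose_thickness_mm Adipose phantom thickness in mm.
#' @param bottom `"silicone_muscle"` or `"intralipid_muscle"`.
#' @param ambient_n Refractive index above the stack.
#' @return A [layered_medium()].
#' @export
phantom_medium <- function(skin_tone, adipose_thickness_mm,
                           bottom = c("silicone_muscle", "intralipid_muscle"),
                           ambient_n = 1.0) {
  bottom <- match.arg(bottom)
  if (!skin_tone %in% names(.phantom_skin))
    stop_bad_arg(sprintf("unknown phantom skin tone '%s'", skin_tone))
  if (adipose_thickness_mm < 0)
    stop_bad_arg("`adipose_thickness_mm` must be >= 0")
  composable <- adipose_thickness_mm %in% c(0:7)
  if (!composable)
    message("adipose thickness not composable from 1/2/4 mm stack elements")
  skin <- optical_layer(paste0(skin_tone, "_skin_phantom"), 1,
                        mua = .phantom_skin[[skin_tone]]$mua,
                        musp = .phantom_skin[[skin_tone]]$musp,
                        g = 0.9, n = 1.40, bfi = 0)
  adipose <- optical_layer("adipose_phantom", adipose_thickness_mm,
                           mua = .phantom_adipose$mua,
                           musp = .phantom_adipose$musp,
                           g = 0.9, n = 1.40, bfi = 0)
  b <- .phantom_bottom[[bottom]]
  bot <- optical_layer(bottom, Inf, mua = b$mua, musp = b$musp,
                       g = b$g, n = b$n, bfi = b$bfi)
  layered_medium(dplyr::bind_rows(skin, adipose, bot), ambient_n = ambient_n)
}

#' Replace the bottom layer's properties
#'
#' Convenience used by the LUT builders and generators: returns a copy of
#' `medium` whose bottom layer takes the supplied values (any of `mua`,
#' `musp`, `bfi`; `mua`/`musp` may be a single number applied to every
#' registered wavelength, or a named per-wavelength vector).
#'
#' @param medium A [layered_medium()].
#' @param mua,musp,bfi Replacement values (optional).
#' @return A [layered_medium()].
#' @export
set_bottom <- function(medium, mua = NULL, musp = NULL, bfi = NULL) {
  i <- nrow(medium)
  expand <- function(v, old) {
    if (is.null(names(v)) && length(v) == 1)
      return(setNames(rep(v, length(old)), names(old)))
    v[order(as.numeric(names(v)))]
  }
  if (!is.null(mua)) medium$mua[[i]] <- expand(mua, medium$mua[[i]])
  if (!is.null(musp)) medium$musp[[i]] <- expand(musp, medium$musp[[i]])
  if (!is.null(bfi)) medium$bfi[i] <- bfi
  medium
}

#' Serialize a medium to a YAML or JSON file
#'
#' Layers are written as ordered records with named fields in mm /
#' mm^-1 / mm^2/s units; the ambient index and wavelength registry travel
#' with the file. `medium_from_file()` restores the medium.
#'
#' @param medium A [layered_medium()].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly (`medium_to_file`); a [layered_medium()]
#'   (`medium_from_file`).
#' @export
medium_to_file <- function(medium, path) {
  rec <- list(
    ambient_n = attr(medium, "ambient_n"),
    wavelengths_nm = attr(medium, "wavelengths_nm"),
    layers = lapply(seq_len(nrow(medium)), function(i) list(
      layer = medium$layer[i],
      thickness_mm = if (is.finite(medium$thickness_mm[i]))
        medium$thickness_mm[i] else "semi-infinite",
      mua = as.list(medium$mua[[i]]),
      musp = as.list(medium$musp[[i]]),
      g = medium$g[i], n = medium$n[i], bfi = medium$bfi[i]
    ))
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname medium_to_file
#' @export
medium_from_file <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- dplyr::bind_rows(lapply(rec$layers, function(l) {
    th <- if (identical(l$thickness_mm, "semi-infinite")) Inf
          else as.numeric(l$thickness_mm)
    optical_layer(l$layer, th,
                  mua = unlist(l$mua), musp = unlist(l$musp),
                  g = l$g, n = l$n, bfi = l$bfi)
  }))
  layered_medium(layers, ambient_n = rec$ambient_n)
}
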