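#' Monte Carlo simulation configuration
#'
#' Holds the transport and detection settings for the layered Monte Carlo
#' engine. The detector is an annulus centred on the source at radius `sds`
#' with half-width `detector_half_width`. Transport is "white": steps are
#' sampled from scattering only and absorption is applied afterwards through
#' Beer-Lambert weights on recorded per-layer pathlengths, so one photon set
#' serves every absorption value on a look-up-table axis.
#'
#' Two variance-reduction controls are exposed. `mua_ref` terminates photons
#' at an exponential reference-absorption path and compensates detected
#' weights by `exp(+mua_ref * total_path)`; this is unbiased for any
#' downstream per-layer absorption and variance-optimal near
#' `mua = mua_ref`. `similarity_depth` switches the deep part of the bottom
#' layer (beyond that many transport mean free paths below its top) to the
#' transport-equivalent reduced medium (`mus = musp`, `g = 0`), which
#' preserves pathlength and momentum-transfer statistics at diffusion scale;
#' set 0 to disable.
#'
#' @param n_photons Photons to launch.
#' @param sds Source-detector separation, mm.
#' @param detector_half_width Annulus half-width, mm.
#' @param seed Integer RNG seed.
#' @param max_total_path Total pathlength cap, mm.
#' @param roulette_threshold,roulette_survival Russian roulette settings for
#'   baked-in absorption mode.
#' @param mua_ref Reference survival absorption, mm^-1 (0 disables).
#' @param similarity_depth Depth, in bottom-layer transport mean free paths,
#'   beyond which similarity-relation transport is used (0 disables).
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_photons = 1e6, sds = 25, detector_half_width = 0.5,
                       seed = 1L, max_total_path = 3000,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       mua_ref = 0.005, similarity_depth = 2) {
  if (n_photons < 1) stop_bad_arg("`n_photons` must be >= 1")
  if (sds <= 0) stop_bad_arg("`sds` must be > 0")
  if (detector_half_width <= 0)
    stop_bad_arg("`detector_half_width` must be > 0")
  if (max_total_path <= sds)
    stop_bad_arg("`max_total_path` must exceed `sds`")
  structure(list(n_photons = n_photons, sds = sds,
                 detector_half_width = detector_half_width,
                 seed = as.integer(seed), max_total_path = max_total_path,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 mua_ref = mua_ref, similarity_depth = similarity_depth),
            class = "sim_config")
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_incident Magnitude of the direction cosine against the
#'   interface normal, in (0, 1].
#' @return Reflection probability in `[0, 1]`; 1 beyond the critical angle.
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (any(n1 < 1) || any(n2 < 1))
    stop_bad_arg("refractive indices must be >= 1")
  if (any(cos_incident <= 0) || any(cos_incident > 1))
    stop_bad_arg("`cos_incident` must be in (0, 1]")
  mapply(.fresnel_reflectance_cpp, n1, n2, cos_incident)
}

# Build the transport zone table for the engine: drop zero-thickness layers,
# optionally split the bottom layer into an exact Henyey-Greenstein margin
# and a deep similarity zone.
build_zones <- function(props, sim, bake_mua = FALSE) {
  keep <- props$thickness_mm > 0
  keep[length(keep)] <- TRUE
  props <- props[keep, , drop = FALSE]
  record_idx <- which(keep)
  nb <- nrow(props)
  zones <- tibble(
    thickness = props$thickness_mm,
    mus = ifelse(props$g < 1, props$musp / (1 - props$g), props$musp),
    g = props$g, n = props$n,
    mua = if (bake_mua) props$mua else rep(0, nb),
    rec = record_idx
  )
  bmusp <- props$musp[nb]
  if (sim$similarity_depth > 0 && bmusp > 0 && props$g[nb] > 0) {
    margin <- sim$similarity_depth / bmusp
    deep <- zones[nb, ]
    deep$mus <- bmusp
    deep$g <- 0
    zones$thickness[nb] <- margin
    zones <- dplyr::bind_rows(zones, deep)
  }
  zones$thickness[nrow(zones)] <- 1e9  # engine treats last zone semi-infinite
  zones
}

#' Run the layered Monte Carlo engine
#'
#' Launches a pencil beam into the layered medium and records, for every
#' photon reaching the detector annulus, the per-layer pathlengths `L`
#' (mm) and per-layer dimensionless momentum transfer
#' `Y = sum(1 - cos(theta))` over scattering events, plus the exit weight.
#' By default the simulation is white in absorption (all layers propagated
#' with `mua = 0`; absorption applied post hoc via [absorption_weights()]),
#' which generalizes white Monte Carlo in the bottom layer to every layer.
#'
#' @param medium A [layered_medium()].
#' @param sim A [sim_config()].
#' @param wavelength Wavelength (nm) selecting the per-layer scattering
#'   properties from the medium's registry.
#' @param bake_mua If `TRUE`, the medium's absorption at `wavelength` is
#'   attenuated continuously along the path instead (validation mode).
#' @return A `photon_batch`: list with matrices `L`, `Y`
#'   (`n_detected x n_layers`), vectors `exit_weight` (reference-absorption
#'   compensated) and `detector_distance`, launch bookkeeping and raw weight
#'   `totals` for conservation checks.
#' @export
run_layered_mc <- function(medium, sim, wavelength, bake_mua = FALSE) {
  if (!inherits(medium, "layered_medium")) stop_bad_arg("invalid medium")
  props <- medium_properties(medium, wavelength)
  if (any(props$musp <= 0))
    warn("non-scattering layer present; detection at a lateral offset is unlikely")
  zones <- build_zones(props, sim, bake_mua = bake_mua)
  res <- .mc_layered_cpp(
    thickness = zones$thickness, mus = zones$mus, g = zones$g,
    n_layer = zones$n, mua_baked = zones$mua,
    n_ambient = attr(medium, "ambient_n"),
    sds = sim$sds, half_width = sim$detector_half_width,
    n_photons = sim$n_photons, max_total_path = sim$max_total_path,
    roulette_threshold = sim$roulette_threshold,
    roulette_survival = sim$roulette_survival,
    mua_ref = sim$mua_ref, seed = sim$seed,
    record_idx = as.integer(zones$rec), n_record = nrow(medium)
  )
  L <- t(res$L); Y <- t(res$Y)
  colnames(L) <- colnames(Y) <- medium$layer
  total_path <- rowSums(L)
  w <- res$exit_weight * exp(sim$mua_ref * total_path)
  if (res$n_detected == 0)
    warn("no photons detected; consider more photons or a wider annulus")
  structure(list(
    L = L, Y = Y, exit_weight = w,
    detector_distance = res$detector_distance,
    n_launched = res$n_launched, n_detected = res$n_detected,
    totals = res$totals,
    layers = medium$layer, n_per_layer = medium$n,
    wavelength = wavelength, sds = sim$sds,
    half_width = sim$detector_half_width, seed = sim$seed,
    mua_ref = sim$mua_ref,
    medium_hash = object_md5(medium_properties(medium, wavelength))
  ), class = "photon_batch")
}

#' @export
print.photon_batch <- function(x, ...) {
  cat(sprintf(
    "<photon_batch> %g launched, %d detected at %.3g mm (wavelength %s nm, seed %d)\n",
    x$n_launched, x$n_detected, x$sds, x$wavelength, x$seed))
  invisible(x)
}

#' Pool independent photon batches
#'
#' Concatenates detected-photon records and sums launch counts; batches must
#' share geometry, wavelength and layer structure.
#'
#' @param batches List of `photon_batch` objects.
#' @return A pooled `photon_batch`.
#' @export
pool_batches <- function(batches) {
  b1 <- batches[[1]]
  for (b in batches[-1]) {
    if (!identical(b$layers, b1$layers) || b$sds != b1$sds ||
        b$wavelength != b1$wavelength || b$mua_ref != b1$mua_ref)
      stop_bad_arg("batches are not poolable")
  }
  out <- b1
  out$L <- do.call(rbind, lapply(batches, `[[`, "L"))
  out$Y <- do.call(rbind, lapply(batches, `[[`, "Y"))
  out$exit_weight <- unlist(lapply(batches, `[[`, "exit_weight"))
  out$detector_distance <- unlist(lapply(batches, `[[`, "detector_distance"))
  out$n_launched <- sum(vapply(batches, `[[`, numeric(1), "n_launched"))
  out$n_detected <- sum(vapply(batches, `[[`, numeric(1), "n_detected"))
  out$totals <- as.list(Reduce(`+`, lapply(batches, function(b)
    unlist(b$totals))))
  out$seed <- b1$seed
  out
}

#' Persist a photon batch to a JSON file
#'
#' Full-precision, version-stamped serialization of the detected-photon
#' records and launch bookkeeping; [load_batch()] restores the batch.
#'
#' @param batch A `photon_batch`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `load_batch()` returns the batch.
#' @export
save_batch <- function(batch, path) {
  payload <- list(
    schema = "mldos_photon_batch", version = 1L,
    layers = batch$layers, n_per_layer = batch$n_per_layer,
    wavelength = batch$wavelength, sds = batch$sds,
    half_width = batch$half_width, seed = batch$seed,
    mua_ref = batch$mua_ref, n_launched = batch$n_launched,
    n_detected = batch$n_detected, totals = batch$totals,
    medium_hash = batch$medium_hash,
    L = batch$L, Y = batch$Y, exit_weight = batch$exit_weight,
    detector_distance = batch$detector_distance
  )
  payload$payload_md5 <- object_md5(payload[c("L", "Y", "exit_weight")])
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_batch
#' @export
load_batch <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "mldos_photon_batch"))
    abort("not an mldos photon batch file", class = "mldos_schema_error")
  md5 <- object_md5(p[c("L", "Y", "exit_weight")])
  if (!identical(md5, p$payload_md5))
    abort("photon batch payload does not match its checksum",
          class = "mldos_provenance_error")
  L <- matrix(p$L, ncol = length(p$layers),
              dimnames = list(NULL, p$layers))
  Y <- matrix(p$Y, ncol = length(p$layers),
              dimnames = list(NULL, p$layers))
  structure(list(
    L = L, Y = Y, exit_weight = p$exit_weight,
    detector_distance = p$detector_distance,
    n_launched = p$n_launched, n_detected = p$n_detected,
    totals = as.list(p$totals), layers = p$layers,
    n_per_layer = p$n_per_layer, wavelength = p$wavelength,
    sds = p$sds, half_width = p$half_width, seed = p$seed,
    mua_ref = p$mua_ref, medium_hash = p$medium_hash
  ), class = "photon_batch")
}
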