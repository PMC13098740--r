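#' Measurement noise configuration for synthetic data
#'
#' The instrument noise model is phenomenological and configurable:
#' multiplicative Gaussian noise on FD amplitude, additive Gaussian noise on
#' FD phase, and additive Gaussian noise on g2 whose standard deviation
#' shrinks with delay as `(tau_min / tau)^0.25`, mimicking the longer
#' effective averaging of larger correlator bins. Amplitude-phase
#' independence is assumed.
#'
#' @param amp_frac Fractional amplitude noise (default 1%).
#' @param phase_sd_rad Phase noise standard deviation, rad (default 2 mrad).
#' @param g2_sigma g2 noise standard deviation at the smallest delay.
#' @return List with class `"noise_config"`.
#' @export
noise_config <- function(amp_frac = 0.01, phase_sd_rad = 0.002,
                         g2_sigma = 2e-3) {
  structure(list(amp_frac = amp_frac, phase_sd_rad = phase_sd_rad,
                 g2_sigma = g2_sigma), class = "noise_config")
}

.fd_freqs <- c("730" = 139e6, "830" = 149e6)

#' Generate a synthetic phantom-stack measurement bundle
#'
#' Emulates the stackable-phantom validation experiment in silico: for each
#' requested skin-tone phantom, adipose thickness and bottom type, the
#' three-layer stack is forward-modelled with the layered Monte Carlo
#' engine to FD reflectance (730 nm at 139 MHz, 830 nm at 149 MHz) and —
#' for the Brownian intralipid bottom — a g2 curve at the phantom coherence
#' factor beta = 0.45. Seeded noise is applied per [noise_config()]; the
#' generating ground truth is embedded in the result.
#'
#' @param tones Character vector of phantom skin tones.
#' @param adipose_mm Integer vector of adipose thicknesses (mm).
#' @param bottoms Subset of `c("silicone_muscle", "intralipid_muscle")`.
#' @param sim A [sim_config()]; per-run photon budget.
#' @param noise A [noise_config()]; use zero fields for noiseless data.
#' @param seed Integer seed controlling both MC streams and noise draws.
#' @param beta Coherence factor recorded and applied to g2.
#' @param tau Delay grid for g2 curves.
#' @return List with class `"phantom_dataset"`: tibbles `fd`, `dcs`,
#'   `truth`, plus the configuration.
#' @export
gen_phantom_dataset <- function(tones = c("light", "medium", "dark"),
                                adipose_mm = 1:6,
                                bottoms = c("silicone_muscle",
                                            "intralipid_muscle"),
                                sim = sim_config(), noise = noise_config(),
                                seed = 1, beta = 0.45,
                                tau = default_tau_grid()) {
  rng_seed <- derive_seed(seed, 77)
  fd <- list(); dcs <- list(); truth <- list()
  k <- 0
  for (bot in bottoms) for (tone in tones) for (ad in adipose_mm) {
    k <- k + 1
    med <- phantom_medium(tone, ad, bot)
    props830 <- medium_properties(med, 830)
    nl <- nrow(props830)
    for (wl in c(730, 830)) {
      sim_s <- sim
      sim_s$seed <- derive_seed(seed, k, wl)
      b <- run_layered_mc(med, sim_s, wl)
      props <- medium_properties(med, wl)
      fmod <- .fd_freqs[[as.character(wl)]]
      z <- fd_from_batch(b, props$mua, fmod) / b$n_launched
      amp <- Mod(z); ph <- -Arg(z)
      set.seed(derive_seed(rng_seed, k, wl))
      amp <- amp * (1 + rnorm(1, 0, noise$amp_frac))
      ph <- ph + rnorm(1, 0, noise$phase_sd_rad)
      fd[[length(fd) + 1]] <- tibble(
        tone = tone, adipose_mm = ad, bottom = bot, wavelength_nm = wl,
        mod_freq_hz = fmod, sds_mm = sim$sds, amplitude = amp,
        phase_rad = ph)
      if (wl == 830 && bot == "intralipid_muscle") {
        g1 <- g1_from_batch(b, props$mua, props$bfi, tau = tau,
                            wavelength = 850)
        g2 <- siegert(g1, beta)
        sig <- noise$g2_sigma * (tau[1] / tau)^0.25
        g2$g2 <- g2$g2 + rnorm(length(tau), 0, sig)
        dcs[[length(dcs) + 1]] <- dplyr::mutate(
          as_tibble(g2), tone = tone, adipose_mm = ad, bottom = bot,
          .before = 1)
      }
    }
    truth[[length(truth) + 1]] <- tibble(
      tone = tone, adipose_mm = ad, bottom = bot,
      mua_730 = medium_properties(med, 730)$mua[nl],
      mua_830 = props830$mua[nl],
      musp_730 = medium_properties(med, 730)$musp[nl],
      musp_830 = props830$musp[nl],
      bfi = props830$bfi[nl], beta = beta)
  }
  structure(list(fd = dplyr::bind_rows(fd), dcs = dplyr::bind_rows(dcs),
                 truth = dplyr::bind_rows(truth),
                 sim = sim, noise = noise, seed = seed),
            class = "phantom_dataset")
}

#' Breathing-exercise protocol description
#'
#' Baseline / load / recovery respiratory protocol sampled at 0.5 Hz:
#' muscle chromophore and blood-flow trajectories sit at their baseline,
#' deviate during the load window along a smoothed trapezoid (linear ramps),
#' and return in recovery.
#'
#' @param baseline_s,load_s,recovery_s Segment durations, s.
#' @param sampling_hz Frame rate, Hz.
#' @param ramp_s Ramp time of the trapezoidal load transient, s.
#' @param baseline Named list of baseline values: `oxy_uM`, `deoxy_uM`,
#'   `bfi` (mm^2/s).
#' @param amplitudes Named list of load-phase deviations (same fields;
#'   signed).
#' @param beta In-vivo coherence factor (~0.35).
#' @return List with class `"breathing_protocol"`.
#' @export
breathing_protocol <- function(baseline_s = 60, load_s = 60,
                               recovery_s = 120, sampling_hz = 0.5,
                               ramp_s = 10,
                               baseline = list(oxy_uM = 90, deoxy_uM = 30,
                                               bfi = 2e-6),
                               amplitudes = list(oxy_uM = -20,
                                                 deoxy_uM = 12,
                                                 bfi = 1.5e-6),
                               beta = 0.35) {
  stopifnot(baseline_s > 0, load_s > 0, recovery_s > 0, sampling_hz > 0)
  structure(list(baseline_s = baseline_s, load_s = load_s,
                 recovery_s = recovery_s, sampling_hz = sampling_hz,
                 ramp_s = ramp_s, baseline = baseline,
                 amplitudes = amplitudes, beta = beta),
            class = "breathing_protocol")
}

# smoothed-trapezoid activation in [0, 1] over the load window
load_shape <- function(t, protocol) {
  t0 <- protocol$baseline_s
  t1 <- t0 + protocol$load_s
  r <- protocol$ramp_s
  up <- pmin(pmax((t - t0) / r, 0), 1)
  down <- pmin(pmax((t1 + r - t) / r, 0), 1)
  pmin(up, down) * (t > t0 & t < t1 + r)
}

#' Generate a synthetic breathing-protocol time series
#'
#' Composes per-frame muscle trajectories (oxy/deoxy chromophores via
#' Beer-Lambert to `mua(730)`/`mua(830)`, plus BFi), forward-models them
#' through the subject's three-layer medium using the supplied multi-layer
#' LUT batches, and applies seeded measurement noise. The generating truth
#' travels with the result, so end-to-end recovery can be scored.
#'
#' @param protocol A [breathing_protocol()].
#' @param subject List with `skin_tone`, `adipose_mm` and `sex`.
#' @param batches A [mc_lut_batches()] set for the subject's tissue medium
#'   at 730 nm and 830 nm, named by wavelength (list of two
#'   `lut_batches`).
#' @param noise A [noise_config()].
#' @param seed Integer seed for the noise streams.
#' @param tau Delay grid for g2 frames.
#' @param musp Muscle reduced scattering per wavelength used for the
#'   generating truth (named vector).
#' @return List with class `"breathing_dataset"`: `fd_frames`,
#'   `dcs_frames`, `truth`, `protocol`, `subject`.
#' @export
gen_breathing_timeseries <- function(protocol, subject, batches,
                                     noise = noise_config(), seed = 1,
                                     tau = default_tau_grid(),
                                     musp = c("730" = 0.75, "830" = 0.70)) {
  total <- protocol$baseline_s + protocol$load_s + protocol$recovery_s
  t <- seq(0, total, by = 1 / protocol$sampling_hz)
  shape <- load_shape(t, protocol)
  oxy <- protocol$baseline$oxy_uM + protocol$amplitudes$oxy_uM * shape
  deoxy <- protocol$baseline$deoxy_uM + protocol$amplitudes$deoxy_uM * shape
  bfi <- protocol$baseline$bfi + protocol$amplitudes$bfi * shape
  mu <- chromophores_to_mua(oxy, deoxy)
  truth <- tibble(frame = seq_along(t), time_s = t, oxy_uM = oxy,
                  deoxy_uM = deoxy, total_uM = oxy + deoxy,
                  sto2_pct = 100 * oxy / (oxy + deoxy), bfi = bfi,
                  mua_730 = mu$mua_730, mua_830 = mu$mua_830,
                  musp_730 = unname(musp["730"]),
                  musp_830 = unname(musp["830"]))

  fd_forwards <- list()
  for (wl in c(730, 830)) {
    bt <- batches[[as.character(wl)]]
    props <- medium_properties(bt$medium, wl)
    upper_mua <- props$mua[-nrow(props)]
    fmod <- .fd_freqs[[as.character(wl)]]
    # dense-in-mua complex responses at the two adjacent musp nodes, then
    # linear interpolation at the truth musp (same scheme as the FD LUT)
    axes_mua <- seq(min(mu[[paste0("mua_", wl)]]) * 0.9,
                    max(mu[[paste0("mua_", wl)]]) * 1.1, length.out = 50)
    nodes <- bt$musp_coarse
    mq <- unname(musp[as.character(wl)])
    i <- max(1L, min(length(nodes) - 1L, findInterval(mq, nodes)))
    fx <- (mq - nodes[i]) / (nodes[i + 1] - nodes[i])
    Ri <- node_fd_over_mua(bt$batches[[i]], upper_mua, axes_mua, fmod)
    Rj <- node_fd_over_mua(bt$batches[[i + 1]], upper_mua, axes_mua, fmod)
    Rq <- (1 - fx) * Ri + fx * Rj
    fd_forwards[[as.character(wl)]] <- list(mua = axes_mua, R = Rq,
                                            mod_freq = fmod)
  }

  set.seed(derive_seed(seed, 99))
  fd_frames <- purrr::map_dfr(seq_along(t), function(fr) {
    purrr::map_dfr(c(730, 830), function(wl) {
      fwd <- fd_forwards[[as.character(wl)]]
      mua_f <- truth[[paste0("mua_", wl)]][fr]
      re <- approx(fwd$mua, Re(fwd$R), xout = mua_f)$y
      im <- approx(fwd$mua, Im(fwd$R), xout = mua_f)$y
      z <- complex(real = re, imaginary = im)
      tibble(frame = fr, time_s = t[fr], wavelength_nm = wl,
             mod_freq_hz = fwd$mod_freq,
             amplitude = Mod(z) * (1 + rnorm(1, 0, noise$amp_frac)),
             phase_rad = -Arg(z) + rnorm(1, 0, noise$phase_sd_rad))
    })
  })

  dcs_fwd <- dcs_forward_from_batches(batches[["830"]], wavelength = 850)
  sig <- noise$g2_sigma * (tau[1] / tau)^0.25
  dcs_frames <- purrr::map_dfr(seq_along(t), function(fr) {
    g1 <- dcs_fwd(truth$mua_830[fr], unname(musp["830"]), truth$bfi[fr],
                  tau)
    tibble(frame = fr, time_s = t[fr], tau_s = tau,
           g2 = 1 + protocol$beta * g1^2 + rnorm(length(tau), 0, sig))
  })

  structure(list(fd_frames = fd_frames, dcs_frames = dcs_frames,
                 truth = truth, protocol = protocol, subject = subject,
                 noise = noise, seed = seed),
            class = "breathing_dataset")
}

#' Baseline and perturbation-magnitude summary of a time series
#'
#' The baseline of each parameter is its mean over the first 50 s; the
#' perturbation magnitude is the largest absolute deviation from baseline
#' inside the load window.
#'
#' @param series Tibble with a `time_s` column and one numeric column per
#'   parameter (non-numeric columns are ignored).
#' @param protocol A [breathing_protocol()] defining the load window.
#' @param baseline_window_s Baseline averaging window (default 50 s).
#' @return Tibble: `parameter`, `baseline`, `perturbation_magnitude`.
#' @export
summarize_timeseries <- function(series, protocol,
                                 baseline_window_s = 50) {
  if (max(series$time_s) < baseline_window_s)
    abort("series shorter than the baseline window",
          class = "mldos_data_error")
  pars <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                  c("time_s", "frame"))
  base_idx <- series$time_s <= baseline_window_s
  load_idx <- series$time_s >= protocol$baseline_s &
    series$time_s <= protocol$baseline_s + protocol$load_s + protocol$ramp_s
  purrr::map_dfr(pars, function(p) {
    v <- series[[p]]
    b <- mean(v[base_idx], na.rm = TRUE)
    tibble(parameter = p, baseline = b,
           perturbation_magnitude =
             if (any(load_idx)) max(abs(v[load_idx] - b), na.rm = TRUE)
             else NA_real_)
  })
}
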