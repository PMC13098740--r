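test_that("phantom bundles are pure functions of their seed", {
  sim <- sim_config(n_photons = 2e4, detector_half_width = 2)
  d1 <- gen_phantom_dataset(tones = "dark", adipose_mm = 2,
                            bottoms = "intralipid_muscle", sim = sim,
                            seed = 5, tau = default_tau_grid(24))
  d2 <- gen_phantom_dataset(tones = "dark", adipose_mm = 2,
                            bottoms = "intralipid_muscle", sim = sim,
                            seed = 5, tau = default_tau_grid(24))
  expect_equal(d1$fd, d2$fd)
  expect_equal(d1$dcs, d2$dcs)
  d3 <- gen_phantom_dataset(tones = "dark", adipose_mm = 2,
                            bottoms = "intralipid_muscle", sim = sim,
                            seed = 6, tau = default_tau_grid(24))
  expect_false(isTRUE(all.equal(d1$fd$amplitude, d3$fd$amplitude)))
  # coherence factor and embedded truth
  expect_equal(unique(d1$truth$beta), 0.45)
  expect_equal(d1$truth$bfi, 1.05e-6)
  expect_equal(d1$truth$mua_830, 0.006)
  expect_setequal(d1$fd$wavelength_nm, c(730, 830))
  expect_equal(sort(unique(d1$fd$mod_freq_hz)), c(139e6, 149e6))
})

test_that("breathing series compose trapezoidal load transients", {
  pr <- breathing_protocol()
  t <- seq(0, 240, by = 2)
  s <- mldos:::load_shape(t, pr)
  expect_true(all(s[t <= 60] == 0))          # baseline flat
  expect_true(all(s[t >= 185] == 0))         # recovered
  expect_equal(max(s), 1)
  expect_true(all(s >= 0 & s <= 1))
  # frame count at 0.5 Hz over 240 s
  bats <- list("730" = tissue_batches(4, 730), "830" = tissue_batches(4, 830))
  ds <- gen_breathing_timeseries(pr, list(skin_tone = "medium",
                                          adipose_mm = 4, sex = "male"),
                                 bats, seed = 3,
                                 tau = default_tau_grid(24))
  expect_equal(nrow(ds$truth), 240 * 0.5 + 1)
  expect_equal(nrow(ds$fd_frames), 2 * nrow(ds$truth))
  # zero perturbation + zero noise gives constant frames
  pr0 <- breathing_protocol(amplitudes = list(oxy_uM = 0, deoxy_uM = 0,
                                              bfi = 0))
  ds0 <- gen_breathing_timeseries(pr0, list(skin_tone = "medium",
                                            adipose_mm = 4, sex = "male"),
                                  bats, seed = 3,
                                  noise = noise_config(0, 0, 0),
                                  tau = default_tau_grid(24))
  expect_equal(length(unique(ds0$fd_frames$amplitude)), 2)  # one per lambda
  expect_equal(sd(ds0$truth$mua_830), 0)
  g2_by_frame <- split(ds0$dcs_frames$g2, ds0$dcs_frames$frame)
  expect_equal(g2_by_frame[[1]], g2_by_frame[[length(g2_by_frame)]])
})

test_that("time-series summaries window the baseline and load phases", {
  pr <- breathing_protocol()
  t <- seq(0, 239, by = 2)
  series <- tibble::tibble(time_s = t,
                           x = ifelse(t < 50, 1, ifelse(t >= 60 & t <= 120,
                                                        1 + 4, 1)))
  s <- summarize_timeseries(series, pr)
  expect_equal(s$baseline[s$parameter == "x"], 1)
  expect_equal(s$perturbation_magnitude[s$parameter == "x"], 4)
  # constant series has zero perturbation
  s0 <- summarize_timeseries(tibble::tibble(time_s = t, y = 7), pr)
  expect_equal(s0$baseline, 7)
  expect_equal(s0$perturbation_magnitude, 0)
  expect_error(summarize_timeseries(tibble::tibble(time_s = 0:40, z = 1), pr),
               class = "mldos_data_error")
})

test_that("noise settings scale the frame-to-frame scatter", {
  bats <- list("730" = tissue_batches(4, 730), "830" = tissue_batches(4, 830))
  pr <- breathing_protocol(recovery_s = 60)
  mk <- function(noise, seed) {
    ds <- gen_breathing_timeseries(pr, list(skin_tone = "medium",
                                            adipose_mm = 4, sex = "male"),
                                   bats, seed = seed, noise = noise,
                                   tau = default_tau_grid(16))
    a <- ds$fd_frames$amplitude[ds$fd_frames$wavelength_nm == 830]
    sd(a[seq_len(25)]) / mean(a[seq_len(25)])
  }
  lo <- mk(noise_config(amp_frac = 0.005), 11)
  hi <- mk(noise_config(amp_frac = 0.03), 11)
  expect_gt(hi, lo)
})
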