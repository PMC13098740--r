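test_that("FD inversion recovers grid nodes exactly and flags boundaries", {
  lut <- hom_fd_lut(830)
  i <- 60; j <- 350
  meas <- tibble::tibble(
    wavelength_nm = 830, mod_freq_hz = 149e6,
    amplitude = Mod(lut$R[i, j]), phase_rad = -Arg(lut$R[i, j]))
  fit <- invert_fd(meas, lut)
  expect_equal(fit$mua, lut$mua_grid[i])
  expect_equal(fit$musp, lut$musp_grid[j])
  expect_lt(fit$objective, 1e-20)
  expect_false(fit$boundary_mua || fit$boundary_musp)
  # off-node interpolated forward recovers within one dense step
  q <- lut_query_fd(lut, 0.0137, 0.7342)
  fit2 <- invert_fd(dplyr::mutate(q, wavelength_nm = 830), lut)
  # the chi-square valley is shallow along musp at a single modulation
  # frequency, so Monte Carlo noise in the LUT can slide the minimum a few
  # dense steps; assert recovery at the level that noise supports
  expect_lt(abs(fit2$mua - 0.0137), 2e-3)
  expect_lt(abs(fit2$musp - 0.7342), 0.02)
  # unreachable bright measurement pins the axis edge and is flagged
  dim_meas <- dplyr::mutate(meas, amplitude = amplitude * 1e3)
  fit3 <- invert_fd(dim_meas, lut)
  expect_true(fit3$boundary_mua || fit3$boundary_musp)
  expect_error(invert_fd(dplyr::mutate(meas, wavelength_nm = 690), lut),
               class = "mldos_invalid_argument")
})

test_that("complex calibration factors are recovered and applied", {
  lut <- hom_fd_lut(830)
  q <- lut_query_fd(lut, 0.03, 0.65)
  cal_true <- 2.5 * exp(-1i * 0.2)
  raw <- dplyr::mutate(q, amplitude = amplitude * Mod(cal_true),
                       phase_rad = phase_rad + 0.2)
  cal <- calibration_factor(raw, q)
  expect_equal(cal * cal_true, 1 + 0i, tolerance = 1e-10)
  fit <- invert_fd(dplyr::mutate(raw, wavelength_nm = 830), lut,
                   calibration = cal)
  expect_equal(fit$mua, 0.03, tolerance = 1e-3)
  expect_equal(fit$musp, 0.65, tolerance = 1e-2)
})

test_that("DCS inversion round-trips and respects the axes", {
  bat <- hom_batches()
  tau <- default_tau_grid(48, c(1e-7, 1e-2))
  lut <- build_dcs_lut(bat$medium, hom_axes(), bat$sim, mua = 0.01,
                       wavelength = 850, tau = tau, batches = bat)
  truth_bfi <- 2.7e-6
  g2 <- lut_query_dcs(lut, 0.7, truth_bfi, beta = 0.45)
  fit <- invert_dcs(g2, lut, musp = 0.7, beta = 0.45)
  expect_equal(fit$bfi, truth_bfi, tolerance = 0.05)
  expect_false(fit$boundary_bfi)
  # undecayed correlation pins the lower BFi bound with a flag
  flat <- structure(tibble::tibble(tau_s = tau, g2 = rep(1.45, length(tau))),
                    class = class(g2))
  fit_flat <- invert_dcs(flat, lut, musp = 0.7, beta = 0.45)
  expect_true(fit_flat$boundary_bfi)
  expect_equal(fit_flat$bfi, min(lut$bfi_grid), tolerance = 0.2)
  # non-physical g2 rejected
  bad <- dplyr::mutate(g2, g2 = g2 - 0.5)
  expect_error(invert_dcs(bad, lut, musp = 0.7, beta = 0.45),
               class = "mldos_data_error")
  # forward-model route with fitted beta recovers both
  fwd <- dcs_forward_from_batches(bat, 850)
  g2b <- siegert(structure(tibble::tibble(
    tau_s = tau, g1 = fwd(0.01, 0.7, truth_bfi, tau)),
    class = c("g1_curve", "tbl_df", "tbl", "data.frame")), 0.35)
  fitb <- invert_dcs(g2b, fwd, mua = 0.01, musp = 0.7, beta = NULL)
  expect_equal(fitb$beta, 0.35, tolerance = 0.02)
  expect_equal(fitb$bfi, truth_bfi, tolerance = 0.05)
})

test_that("time-series fitting is frame-independent and failure-tolerant", {
  lut <- hom_fd_lut(830)
  q <- lut_query_fd(lut, 0.04, 0.55)
  frames <- dplyr::bind_rows(lapply(1:4, function(fr) tibble::tibble(
    frame = fr, time_s = (fr - 1) * 2, wavelength_nm = 830,
    mod_freq_hz = 149e6, amplitude = q$amplitude, phase_rad = q$phase_rad)))
  fits <- fit_timeseries(frames, list("830" = lut))
  expect_equal(nrow(fits), 4)
  expect_equal(unique(fits$mua_830), 0.04, tolerance = 1e-6)
  expect_equal(unique(fits$musp_830), 0.55, tolerance = 1e-6)
  # permutation of frame order yields the same per-frame results
  fits_perm <- fit_timeseries(frames[sample(nrow(frames)), ],
                              list("830" = lut))
  expect_equal(fits_perm, fits)
  # a broken frame is marked, not fatal
  frames$amplitude[frames$frame == 3] <- NA
  fits3 <- suppressWarnings(fit_timeseries(frames, list("830" = lut)))
  expect_false(fits3$ok[3])
  expect_true(all(fits3$ok[-3]))
})
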