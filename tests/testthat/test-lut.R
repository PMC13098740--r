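test_that("LUT axes have the prescribed densification", {
  ax <- lut_axes()
  expect_equal(ax$musp_coarse, seq(0.1, 1.0, by = 0.1))
  expect_equal(length(ax$musp_dense_fd), 901)   # 0.1-1.0 at 0.001
  expect_equal(length(ax$musp_dense_dcs), (1.0 - 0.1) / 0.05 + 1)
  expect_true(all(round(ax$musp_coarse, 9) %in% round(ax$musp_dense_fd, 9)))
  expect_equal(range(ax$mua_grid), c(0.01, 0.2))
  expect_equal(range(ax$bfi_grid), c(0.1e-6, 40e-6), tolerance = 1e-9)
})

test_that("FD LUT is self-consistent at coarse nodes and monotone in mua", {
  lut <- hom_fd_lut(830)
  bat <- hom_batches()
  ax <- hom_axes()
  # querying a coarse node reproduces the node value computed from scratch
  node <- 5
  direct <- mldos:::node_fd_over_mua(bat$batches[[node]], numeric(0),
                                     ax$mua_grid, 149e6) /
    1  # already per launched photon
  j <- which(abs(lut$musp_grid - ax$musp_coarse[node]) < 1e-12)
  expect_equal(lut$R[, j], direct, tolerance = 1e-12)
  q <- lut_query_fd(lut, 0.05, ax$musp_coarse[node])
  i <- which(abs(lut$mua_grid - 0.05) < 1e-12)
  expect_equal(q$amplitude, Mod(lut$R[i, j]), tolerance = 1e-12)
  # Beer weighting makes amplitude strictly decreasing along the mua axis
  expect_true(all(diff(Mod(lut$R)) < 0))
})

test_that("LUT building is deterministic in the seed set", {
  med <- hom_medium(ambient_n = 1.0)
  ax <- lut_axes(musp_range = c(0.6, 0.8))
  sim <- sim_config(n_photons = 1e4, detector_half_width = 2, seed = 3)
  l1 <- build_fd_lut(med, ax, sim, 830, 149e6, n_repeats = 2)
  l2 <- build_fd_lut(med, ax, sim, 830, 149e6, n_repeats = 2)
  expect_identical(l1$R, l2$R)
})

test_that("pooling batches concatenates photons and sums launches", {
  sim <- sim_config(n_photons = 5e3, detector_half_width = 2, seed = 1)
  med <- hom_medium()
  b1 <- run_layered_mc(med, sim, 830)
  sim$seed <- 2L
  b2 <- run_layered_mc(med, sim, 830)
  p <- pool_batches(list(b1, b2))
  expect_equal(p$n_launched, b1$n_launched + b2$n_launched)
  expect_equal(p$n_detected, b1$n_detected + b2$n_detected)
  expect_equal(nrow(p$L), p$n_detected)
  expect_equal(p$totals$detected, b1$totals$detected + b2$totals$detected)
  expect_error(pool_batches(list(b1, run_layered_mc(med, sim, 730))),
               class = "mldos_invalid_argument")
})

test_that("LUT persistence round-trips bit-identically and checks provenance", {
  lut <- hom_fd_lut(830)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  save_lut(lut, p1)
  back <- load_lut(p1)
  expect_identical(back$R, lut$R)
  expect_identical(back$mua_grid, lut$mua_grid)
  save_lut(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # tampered payload is rejected
  txt <- readLines(p1, warn = FALSE)
  txt <- sub("\"R_re\":\\[\\[([0-9eE+.-]+)", "\"R_re\":[[1.0", txt)
  writeLines(txt, p1)
  expect_error(load_lut(p1), class = "mldos_provenance_error")
  # truncated file fails cleanly
  writeLines(substr(paste(txt, collapse = ""), 1, 500), p1)
  expect_error(load_lut(p1))
  expect_no_error(load_lut(p2))
  unlink(c(p1, p2))
})

test_that("DCS LUT curves are monotone in BFi and match the oracle", {
  bat <- hom_batches()
  ax <- hom_axes()
  tau <- default_tau_grid(48, c(1e-7, 1e-2))
  lut <- build_dcs_lut(bat$medium, ax, bat$sim, mua = 0.01,
                       wavelength = 850, tau = tau, batches = bat)
  expect_equal(dim(lut$g1sq), c(length(ax$musp_dense_dcs),
                                length(ax$bfi_grid), length(tau)))
  g2_slow <- lut_query_dcs(lut, 1.0, min(lut$bfi_grid), beta = 0.45)
  g2_fast <- lut_query_dcs(lut, 1.0, max(lut$bfi_grid), beta = 0.45)
  expect_true(all(g2_slow$g2 >= g2_fast$g2 - 1e-12))
  expect_true(all(g2_slow$g2 >= 1 - 1e-12 & g2_slow$g2 <= 1.45 + 1e-12))
  # homogeneous-template curve agrees with correlation diffusion
  g1sq <- mldos:::dcs_g1sq_at(lut, 1.0, 1e-6)
  g1th <- diffusion_g1_semi_infinite(0.01, 1.0, 1.4, 25, 1e-6, 850,
                                     tau = tau)
  expect_lt(sqrt(mean((sqrt(g1sq) - g1th$g1)^2)), 0.03)
})
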