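test_that("absorption weights follow Beer-Lambert on recorded pathlengths", {
  b <- oracle_batch()
  w0 <- absorption_weights(b, 0)
  expect_equal(w0, b$exit_weight)
  # single-photon analytic check: L = (1, 2, 10) mm at tabulated light-skin
  # 730 nm upper-layer values gives multiplier exp(-0.139)
  fake <- list(L = matrix(c(1, 2, 10), nrow = 1), exit_weight = 1,
               n_per_layer = c(1.4, 1.44, 1.38))
  w <- fake$exit_weight * exp(-drop(fake$L %*% c(0.019, 0.010, 0.010)))
  expect_equal(w, exp(-0.139), tolerance = 1e-12)
  expect_equal(w, 0.8702, tolerance = 1e-3)
  expect_error(absorption_weights(b, c(0.1, 0.2)))
  expect_error(absorption_weights(b, -0.1), class = "mldos_invalid_argument")
})

test_that("the TOF histogram conserves weight at any binning", {
  b <- oracle_batch()
  w <- absorption_weights(b, 0.01)
  h1 <- tof_histogram(b, w, bin_width_ns = 0.01)
  h2 <- tof_histogram(b, w, bin_width_ns = 0.005)
  expect_equal(sum(h1$weight), sum(w))
  expect_equal(sum(h2$weight), sum(w))
  expect_true(all(diff(h1$t_mid_ns) > 0))
  # single photon lands in exactly one bin
  b1 <- b; b1$L <- b$L[1, , drop = FALSE]; b1$exit_weight <- b$exit_weight[1]
  h <- tof_histogram(b1, b1$exit_weight, bin_width_ns = 0.05)
  expect_equal(sum(h$weight > 0), 1)
  expect_equal(sum(h$weight), b1$exit_weight)
})

test_that("FD reflectance reduces to total weight at zero frequency", {
  b <- oracle_batch()
  w <- absorption_weights(b, 0.01)
  h <- tof_histogram(b, w)
  fd0 <- fd_reflectance(h, 0)
  expect_equal(fd0$amplitude, sum(w))
  expect_equal(fd0$phase_rad, 0)
  # phase grows with modulation frequency
  p139 <- fd_reflectance(h, 139e6)$phase_rad
  p149 <- fd_reflectance(h, 149e6)$phase_rad
  expect_gt(p139, 0)
  expect_gt(p149, p139)
})

test_that("the Siegert relation maps g1 to g2", {
  expect_equal(siegert(1, 0.45), 1.45)
  expect_equal(siegert(0, 0.45), 1)
  expect_equal(siegert(c(1, 0.5, 0), 0), c(1, 1, 1))
  g1 <- structure(tibble::tibble(tau_s = c(1e-6, 1e-5), g1 = c(0.9, 0.5)),
                  class = c("g1_curve", class(tibble::tibble())))
  g2 <- siegert(g1, 0.35)
  expect_equal(g2$g2, 1 + 0.35 * c(0.81, 0.25))
  expect_error(siegert(g1, 1.2), class = "mldos_invalid_argument")
})

test_that("batch g1 obeys the Brownian-dynamics limits", {
  b <- oracle_batch()
  tau <- c(0, default_tau_grid(32, c(1e-7, 1e-2)))
  g1 <- g1_from_batch(b, 0.01, 1e-6, tau = tau, wavelength = 850)
  expect_equal(g1$g1[1], 1)
  expect_true(all(diff(g1$g1) <= 1e-12))    # non-increasing
  g1_static <- g1_from_batch(b, 0.01, 0, tau = tau)
  expect_equal(g1_static$g1, rep(1, length(tau)))
  g1_fast <- g1_from_batch(b, 0.01, 4e-6, tau = tau)
  expect_true(all(g1_fast$g1[-1] < g1$g1[-1]))   # faster flow, faster decay
  expect_error(g1_from_batch(b, 0.01, -1e-6),
               class = "mldos_invalid_argument")
})

test_that("closed-form diffusion oracles behave analytically", {
  z0 <- diffusion_fd_semi_infinite(0.01, 1, 1.4, 25, 0)
  expect_equal(Im(z0), 0, tolerance = 1e-15)
  zf <- diffusion_fd_semi_infinite(0.01, 1, 1.4, 25, 139e6)
  expect_equal(Mod(diffusion_fd_semi_infinite(0.01, 1, 1.4, 25, 1)), Re(z0),
               tolerance = 1e-6)
  expect_gt(-Arg(zf), 0)
  # amplitude strictly decreasing in mua
  amps <- sapply(seq(0.005, 0.05, by = 0.005), function(m)
    Re(diffusion_fd_semi_infinite(m, 1, 1.4, 25, 0)))
  expect_true(all(diff(amps) < 0))
  g1 <- diffusion_g1_semi_infinite(0.01, 1, 1.4, 25, 1e-6, 850,
                                   tau = c(0, default_tau_grid(32)))
  expect_equal(g1$g1[1], 1)
  g1f <- diffusion_g1_semi_infinite(0.01, 1, 1.4, 25, 3e-6, 850,
                                    tau = c(0, default_tau_grid(32)))
  expect_true(all(g1f$g1[-1] <= g1$g1[-1] + 1e-12))
  expect_equal(diffusion_g1_semi_infinite(0.01, 1, 1.4, 25, 0)$g1,
               rep(1, 64))
})

test_that("the N-layer Hankel solution collapses to the semi-infinite forms", {
  # single layer: phase and log-amplitude derivative match the closed form
  h1 <- diffusion_fd_nlayer(0.01, 1.0, numeric(0), n = 1.4, rho = 25,
                            mod_freq_hz = 149e6)
  c1 <- diffusion_fd_semi_infinite(0.01, 1, 1.4, 25, 149e6)
  expect_equal(-Arg(h1) * 180 / pi, -Arg(c1) * 180 / pi, tolerance = 0.03)
  h2 <- diffusion_fd_nlayer(0.02, 1.0, numeric(0), n = 1.4, rho = 25,
                            mod_freq_hz = 149e6)
  c2 <- diffusion_fd_semi_infinite(0.02, 1, 1.4, 25, 149e6)
  expect_equal(log(Mod(h2) / Mod(h1)), log(Mod(c2) / Mod(c1)),
               tolerance = 0.02)
  # degenerate stack of identical layers equals the single layer
  h3 <- diffusion_fd_nlayer(c(0.01, 0.01, 0.01), c(1, 1, 1), c(1, 2),
                            n = 1.4, rho = 25, mod_freq_hz = 149e6)
  expect_equal(Mod(h3) / Mod(h1), 1, tolerance = 1e-6)
  expect_equal(Arg(h3), Arg(h1), tolerance = 1e-6)
})

test_that("mean time of flight matches diffusion theory", {
  b <- oracle_batch()
  w <- absorption_weights(b, 0.01)
  t_mean <- sum(w * mldos:::photon_times_ns(b)) / sum(w)
  t_th <- diffusion_mean_tof_ns(0.01, 1, 1.4, 25, n_ambient = 1.4)
  expect_equal(t_mean / t_th, 1, tolerance = 0.05)
})
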