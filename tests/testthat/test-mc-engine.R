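test_that("Fresnel reflectance has the right closed-form limits", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.5), 0)
  expect_equal(fresnel_reflectance(1.0, 1.4, 1.0), (0.4 / 2.4)^2,
               tolerance = 1e-12)
  # total internal reflection beyond the critical angle
  cos_c <- sqrt(1 - (1 / 1.4)^2)
  expect_equal(fresnel_reflectance(1.4, 1.0, cos_c * 0.9), 1)
  expect_true(fresnel_reflectance(1.4, 1.0, cos_c * 1.05) < 1)
  expect_error(fresnel_reflectance(0.5, 1.4, 1), class = "mldos_invalid_argument")
})

test_that("launched weight is conserved across the exit channels", {
  sim <- sim_config(n_photons = 5e4, detector_half_width = 2, seed = 3,
                    mua_ref = 0)   # pure white transport, no survival kills
  b <- run_layered_mc(tissue_medium("dark", 2), sim, 830)
  tot <- b$totals
  acc <- tot$specular + tot$detected + tot$escaped + tot$killed +
    tot$absorbed + tot$absorbed_ref
  expect_equal(acc / b$n_launched, 1, tolerance = 1e-9)
  expect_equal(tot$absorbed, 0)    # white in absorption
})

test_that("identical seeds reproduce batches; different seeds differ", {
  sim <- sim_config(n_photons = 2e4, detector_half_width = 2, seed = 42)
  med <- tissue_medium("medium", 1)
  b1 <- run_layered_mc(med, sim, 830)
  b2 <- run_layered_mc(med, sim, 830)
  expect_identical(b1$L, b2$L)
  expect_identical(b1$Y, b2$Y)
  expect_identical(b1$exit_weight, b2$exit_weight)
  sim$seed <- 43L
  b3 <- run_layered_mc(med, sim, 830)
  expect_false(b3$n_detected == b1$n_detected &&
                 isTRUE(all.equal(b3$L, b1$L)))
  # detected counts agree within generous binomial error
  expect_lt(abs(b3$n_detected - b1$n_detected),
            8 * sqrt(max(b1$n_detected, 1)))
})

test_that("splitting a layer into identical sublayers changes nothing", {
  l1 <- optical_layer("skin", 1, mua = c("830" = 0.02),
                      musp = c("830" = 1.2), g = 0.9, n = 1.4, bfi = 0)
  adip <- function(th) optical_layer(paste0("a", th), th,
                                     mua = c("830" = 0.01),
                                     musp = c("830" = 1.1),
                                     g = 0.9, n = 1.44, bfi = 0)
  bot <- optical_layer("muscle", Inf, mua = c("830" = 0.02),
                       musp = c("830" = 0.7), g = 0.9, n = 1.38, bfi = 2e-6)
  med_merged <- layered_medium(dplyr::bind_rows(l1, adip(2), bot))
  med_split <- layered_medium(dplyr::bind_rows(l1, adip(1), adip(1), bot))
  sim <- sim_config(n_photons = 2e4, detector_half_width = 2, seed = 11,
                    similarity_depth = 0)
  bm <- run_layered_mc(med_merged, sim, 830)
  bs <- run_layered_mc(med_split, sim, 830)
  expect_equal(bs$n_detected, bm$n_detected)
  # per-photon sublayer sums equal the merged layer exactly
  expect_equal(bs$L[, 2] + bs$L[, 3], bm$L[, 2], tolerance = 1e-12)
  expect_equal(bs$Y[, 2] + bs$Y[, 3], bm$Y[, 2], tolerance = 1e-12)
  expect_equal(bs$L[, c(1, 4)], bm$L[, c(1, 3)], ignore_attr = TRUE)
})

test_that("non-scattering media yield no photons at a lateral detector", {
  med <- layered_medium(optical_layer(
    "void", Inf, mua = c("830" = 0.01), musp = c("830" = 0),
    g = 0, n = 1.4, bfi = 0))
  sim <- sim_config(n_photons = 5e3, detector_half_width = 2, seed = 2,
                    max_total_path = 100, similarity_depth = 0)
  # warns both about the non-scattering layer and the empty detection
  expect_warning(expect_warning(b <- run_layered_mc(med, sim, 830)))
  expect_equal(b$n_detected, 0)
})

test_that("momentum transfer is zero wherever pathlength is zero", {
  sim <- sim_config(n_photons = 5e4, detector_half_width = 2, seed = 7)
  b <- run_layered_mc(tissue_medium("light", 1), sim, 830)
  for (j in seq_len(ncol(b$L))) {
    expect_true(all(b$Y[b$L[, j] == 0, j] == 0))
    expect_true(all(b$L[, j] >= 0) && all(b$Y[, j] >= 0))
  }
  expect_true(all(b$detector_distance >= 23 & b$detector_distance <= 27))
  # at a short separation under a thick overburden some detected photons
  # never enter the muscle, and their bottom-layer books stay empty
  sim5 <- sim_config(n_photons = 2e4, sds = 5, detector_half_width = 1,
                     seed = 8)
  b5 <- run_layered_mc(tissue_medium("light", 6), sim5, 830)
  expect_true(any(b5$L[, 3] == 0))
  expect_true(all(b5$Y[b5$L[, 3] == 0, 3] == 0))
})

test_that("baked-in absorption equals post-hoc Beer reweighting", {
  med <- tissue_medium("medium", 1)
  # roulette disabled so the RNG streams stay aligned between the two modes
  sim <- sim_config(n_photons = 5e4, detector_half_width = 2, seed = 13,
                    max_total_path = 400, mua_ref = 0,
                    roulette_threshold = 0)
  bw <- run_layered_mc(med, sim, 830)
  bb <- run_layered_mc(med, sim, 830, bake_mua = TRUE)
  expect_equal(bb$n_detected, bw$n_detected)
  w_post <- absorption_weights(bw, medium_properties(med, 830)$mua)
  expect_equal(bb$exit_weight, w_post, tolerance = 1e-10)
})

test_that("reference-absorption compensation is unbiased", {
  med <- hom_medium(ambient_n = 1.0)
  mk <- function(ref, seed) {
    sim <- sim_config(n_photons = 4e5, detector_half_width = 2, seed = seed,
                      mua_ref = ref)
    b <- run_layered_mc(med, sim, 830)
    sum(absorption_weights(b, 0.02)) / b$n_launched
  }
  r_ref <- mean(c(mk(0.005, 1), mk(0.005, 2)))
  r_white <- mean(c(mk(0, 3), mk(0, 4)))
  expect_equal(r_ref / r_white, 1, tolerance = 0.1)
})
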