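test_that("ITA classification matches the colorimetric thresholds", {
  expect_equal(classify_ita(50), "light")
  expect_equal(classify_ita(-17.8), "dark")
  expect_equal(classify_ita(25), "medium")
  # boundary values belong to the closed medium interval
  expect_equal(classify_ita(c(10, 41)), c("medium", "medium"))
  expect_equal(classify_ita(c(41.0001, 9.9999)), c("light", "dark"))
  expect_error(classify_ita(NaN), class = "mldos_invalid_argument")
  expect_error(classify_ita(Inf), class = "mldos_invalid_argument")
})

test_that("tissue presets reproduce the tabulated layer properties", {
  med <- tissue_medium("dark", 2)
  p730 <- medium_properties(med, 730)
  p830 <- medium_properties(med, 830)
  expect_equal(p730$mua[1], 0.149)
  expect_equal(p730$musp[1], 1.34)
  expect_equal(p830$mua[1], 0.044)
  expect_equal(p830$musp[1], 1.17)
  expect_equal(p730$thickness_mm[1], 1)        # static skin thickness
  expect_equal(p830$mua[2], 0.010)             # adipose
  expect_equal(p830$musp[2], 1.09)
  expect_equal(med$n[2], 1.44)
  expect_equal(med$bfi[1:2], c(0.6e-6, 0.6e-6))
  expect_equal(med$n[3], 1.38)
  light <- tissue_medium("light", 1)
  expect_equal(medium_properties(light, 730)$mua[1], 0.019)
  expect_equal(medium_properties(light, 830)$mua[1], 0.006)
  expect_equal(medium_properties(tissue_medium("medium", 1), 830)$mua[1],
               0.017)
  expect_error(tissue_medium("olive", 1), class = "mldos_invalid_argument")
  expect_warning(tissue_medium("light", 8), "beyond")
})

test_that("phantom presets reproduce the tabulated phantom properties", {
  med <- phantom_medium("dark", 4, "silicone_muscle")
  expect_equal(medium_properties(med, 830)$mua[1], 0.073)
  expect_equal(medium_properties(med, 730)$mua[1], 0.106)
  expect_equal(medium_properties(med, 830)$musp[3], 0.38)
  expect_equal(medium_properties(med, 730)$mua[3], 0.041)
  expect_equal(med$bfi, c(0, 0, 0))            # all-silicone stack is static
  il <- phantom_medium("light", 1, "intralipid_muscle")
  expect_equal(il$bfi[3], 1.05e-6)
  expect_equal(il$g[3], 0.61)
  expect_equal(il$n[3], 1.37)
  expect_equal(medium_properties(il, 830)$mua[1], 0.007)
  expect_equal(medium_properties(il, 730)$musp[1], 1.62)
  # 1 mm skin + 6 mm adipose overburden
  m6 <- phantom_medium("medium", 6, "silicone_muscle")
  expect_equal(sum(m6$thickness_mm[1:2]), 7)
  expect_error(phantom_medium("dark", 2, "water"))
})

test_that("a zero-thickness layer is dropped from transport but kept in the books", {
  med0 <- tissue_medium("medium", 0)
  zones <- mldos:::build_zones(medium_properties(med0, 830),
                               sim_config(similarity_depth = 0))
  expect_equal(nrow(zones), 2)                 # skin + muscle only
  expect_equal(zones$rec, c(1, 3))             # bookkeeping maps to 3 layers
  sim <- sim_config(n_photons = 2e4, detector_half_width = 2, seed = 9)
  b0 <- run_layered_mc(med0, sim, 830)
  expect_equal(ncol(b0$L), 3)
  expect_true(all(b0$L[, 2] == 0))             # no path in absent adipose
})

test_that("media round-trip through YAML and JSON files", {
  med <- tissue_medium("light", 3)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    medium_to_file(med, path)
    back <- medium_from_file(path)
    expect_equal(medium_properties(back, 830), medium_properties(med, 830))
    expect_equal(attr(back, "ambient_n"), attr(med, "ambient_n"))
    unlink(path)
  }
})

test_that("set_bottom replaces only the bottom layer", {
  med <- tissue_medium("medium", 2)
  med2 <- set_bottom(med, mua = 0.05, musp = c("730" = 0.5, "830" = 0.45),
                     bfi = 5e-6)
  expect_equal(medium_properties(med2, 830)$mua[3], 0.05)
  expect_equal(medium_properties(med2, 730)$musp[3], 0.5)
  expect_equal(med2$bfi[3], 5e-6)
  expect_equal(medium_properties(med2, 830)$mua[1:2],
               medium_properties(med, 830)$mua[1:2])
})
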