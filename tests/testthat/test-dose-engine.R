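test_that("weighting config validates fields and round-trips as JSON", {
  cfg <- weighting_config()
  expect_equal(cfg$cbe_tumor, 3.8)
  expect_equal(cfg$brain_dose_limit, 12.5)
  expect_error(weighting_config(cbe_tumor = -1), "positive")
  expect_error(weighting_config(nonsense = 2), "unknown")
  f <- tempfile(fileext = ".json")
  write_weighting_config(weighting_config(blood_boron = 30), f)
  expect_equal(read_weighting_config(f)$blood_boron, 30)
  ship <- system.file("extdata", "weights_default.json", package = "beamlab")
  expect_equal(read_weighting_config(ship), cfg)
})

test_that("zero fluence gives identically zero dose components", {
  src <- mono_pencil_source(100)
  sc <- build_scene(NULL, phantom_material = "void",
                    background_material = "void", collimator_length_cm = 2)
  b <- run_transport(src, sc, run_spec(10, seed = 1, photon_transport = FALSE),
                     tally = list(origin = c(5, 5, 5), dims = c(2L, 2L, 2L),
                                  d = c(1, 1, 1)))  # off-beam mesh
  comp <- compute_dose_components(b)
  expect_equal(sum(abs(comp$boron)) + sum(abs(comp$nitrogen)) +
                 sum(abs(comp$hydrogen)) + sum(abs(comp$gamma)), 0)
})

test_that("boron dose matches the single-voxel hand calculation", {
  # uniform 1/v-folded fluence phi in brain at 25 ug/g: D_B =
  # (ppm 1e-6 N_A / M_B10) sigma0 Qbar phi, converted to Gy/h at strength S
  b <- water_bundle()
  comp <- compute_dose_components(b, boron_ppm = 25, strength = 2e11)
  k <- nuclear_constants()
  i <- c(10, 10, 5)
  phi <- b$onev_sub[i[1], i[2], i[3]] + b$onev_epi[i[1], i[2], i[3]]
  nb_per_g <- 25e-6 * k$meta$avogadro / k$nuclides$B10$atomic_mass
  want <- phi * nb_per_g * (k$nuclides$B10$sigma0_capture * 1e-24) *
    k$kerma_constants_MeV$B10_NA * 1.602176634e-10 * 2e11 * 3600
  expect_equal(comp$boron[i[1], i[2], i[3]], want, tolerance = 1e-9)
})

test_that("boron dose is linear in concentration, other components fixed", {
  b <- water_bundle()
  c1 <- compute_dose_components(b, boron_ppm = 25)
  c2 <- compute_dose_components(b, boron_ppm = 50)
  expect_equal(c2$boron, 2 * c1$boron, tolerance = 1e-12)
  expect_identical(c2$nitrogen, c1$nitrogen)
  expect_identical(c2$hydrogen, c1$hydrogen)
  expect_identical(c2$gamma, c1$gamma)
  expect_error(compute_dose_components(b, boron_ppm = array(1, c(2, 2, 2))),
               "shape")
})

test_that("weighting follows the four-term rule", {
  cfg <- weighting_config()
  cb <- fake_components(boron = 1)
  expect_equal(unique(as.numeric(weight_dose(cb, cfg, "tumor"))), 3.8)
  expect_equal(unique(as.numeric(weight_dose(cb, cfg, "skin"))), 2.5)
  expect_equal(unique(as.numeric(weight_dose(cb, cfg, "normal"))), 1.34)
  z <- fake_components(0, 0, 0, 0)
  expect_equal(sum(abs(weight_dose(z, cfg, "tumor"))), 0)
  u <- fake_components(1, 1, 1, 1)
  expect_equal(unique(as.numeric(weight_dose(u, cfg, "normal"))),
               1 + 3 + 3 + 1.34)
  # identity configuration reproduces the physical total
  id <- weighting_config(rbe_nitrogen = 1, rbe_hydrogen = 1, rbe_gamma = 1,
                         cbe_tumor = 1, cbe_skin = 1, cbe_normal = 1,
                         tumor_to_blood = 1, skin_to_blood = 1)
  r <- fake_components(0.2, 0.3, 0.4, 0.5)
  expect_equal(as.numeric(weight_dose(r, id, "tumor")),
               as.numeric(total_dose(r)), tolerance = 1e-12)
  expect_equal(as.numeric(role_dose_map(r, id, "tumor")),
               as.numeric(total_dose(r)), tolerance = 1e-12)
})

test_that("tumor/normal construct: degenerate equality and dominance", {
  b <- water_bundle()
  comp <- compute_dose_components(b)
  cfg_eq <- weighting_config(tumor_to_blood = 1, cbe_tumor = 1.34)
  pr <- tumor_dose_profile(comp, cfg_eq)
  expect_equal(pr$tumor$value, pr$normal$value, tolerance = 1e-12)
  cfg <- weighting_config()
  pr2 <- tumor_dose_profile(comp, cfg)
  sel <- pr2$tumor$depth < 15   # statistically meaningful depths
  expect_true(all(pr2$tumor$value[sel] > pr2$normal$value[sel]))
  # ratio bounded by cbe_tumor*ratio/cbe_normal where boron dominates
  ratio <- pr2$tumor$value[sel] / pr2$normal$value[sel]
  expect_true(all(ratio >= 1 - 1e-12))
  expect_true(all(ratio <= cfg$cbe_tumor * cfg$tumor_to_blood /
                    cfg$cbe_normal + 1e-12))
})

test_that("boron share of the tumor dose exceeds 0.9 at therapeutic depths", {
  b <- water_bundle()
  cfg <- weighting_config()
  comp <- compute_dose_components(b)
  cp <- component_profiles(comp)
  sel <- cp$depth > 1 & cp$depth < 8
  share <- (cfg$cbe_tumor * cfg$tumor_to_blood * cp$boron[sel]) /
    (cfg$cbe_tumor * cfg$tumor_to_blood * cp$boron[sel] +
       3 * cp$nitrogen[sel] + 3 * cp$hydrogen[sel] + cp$gamma[sel])
  expect_true(all(share > 0.9))
})

test_that("dose maps are linear in source strength", {
  b <- water_bundle()
  c1 <- compute_dose_components(b, strength = 1e11)
  c2 <- compute_dose_components(b, strength = 2e11)
  expect_equal(2 * total_dose(c1), total_dose(c2), tolerance = 1e-12)
})
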