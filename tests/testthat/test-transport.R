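test_that("single pencil track in void scores bin length over voxel volume", {
  sc <- build_scene(NULL, phantom_material = "void",
                    background_material = "void", collimator_length_cm = 2)
  src <- mono_pencil_source(100)
  b <- run_transport(src, sc, run_spec(1, seed = 1, photon_transport = FALSE),
                     tally = list(origin = c(-1, -1, 0), dims = c(1L, 1L, 10L),
                                  d = c(2, 2, 2)))
  expect_equal(as.numeric(b$neutron$value[1, 1, , 2]), rep(2 / 8, 10),
               tolerance = 1e-5)
})

test_that("pure-absorber transmission follows Beer-Lambert", {
  absorber_material()
  sc <- build_scene(NULL, phantom_material = "absorber", phantom_size_cm = 10,
                    collimator_length_cm = 2, background_material = "void")
  src <- make_epithermal_source(1, 0, 0, group_bounds = c(0.0252, 0.0254),
                                disc_radius = 0.5, angular_exponent = Inf,
                                plane_z = -1, neutron_gamma_ratio = 1e12)
  n <- 4e4
  b <- run_transport(src, sc, run_spec(n, seed = 5, photon_transport = FALSE),
                     tally = list(origin = c(-1, -1, 0), dims = c(1L, 1L, 1L),
                                  d = c(2, 2, 10)))
  SigC <- macroscopic_xs("absorber", 0.0253)$capture
  p <- exp(-SigC * 10)
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(b$counters$escaped - n * p), 4 * se)
})

test_that("analog histories partition exactly into absorbed and escaped", {
  b <- water_bundle()
  expect_equal(b$counters$absorbed + b$counters$escaped,
               b$counters$n_primaries)
  expect_equal(b$counters$n_primaries + b$counters$g_primaries,
               b$counters$histories)
})

test_that("same seed and config give bit-identical tallies", {
  src <- fixture_source()
  sc <- build_scene(NULL, phantom_material = "water")
  rs <- run_spec(2e4, seed = 12)
  b1 <- run_transport(src, sc, rs, tally_mesh(sc, c(2, 2, 1)))
  b2 <- run_transport(src, sc, rs, tally_mesh(sc, c(2, 2, 1)))
  expect_identical(b1$neutron$value, b2$neutron$value)
  expect_identical(b1$photon$edep, b2$photon$edep)
})

test_that("fine-mesh tallies integrate to the coarse tally", {
  src <- fixture_source()
  sc <- build_scene(NULL, phantom_material = "water")
  rs <- run_spec(2e4, seed = 3)
  co <- run_transport(src, sc, rs, tally_mesh(sc, c(2, 2, 1)))
  fi <- run_transport(src, sc, rs, tally_mesh(sc, c(2, 2, 0.5)))
  f <- fi$neutron$value[, , , 1]
  agg <- (f[, , seq(1, 40, 2)] + f[, , seq(2, 40, 2)]) / 2
  expect_equal(agg, co$neutron$value[, , , 1], tolerance = 1e-9)
})

test_that("thermal axial profile shows sub-surface build-up then decay", {
  b <- water_bundle()
  p <- axial_profile(b, "thermal", radius = 2)
  ipk <- which.max(p$value)
  expect_gt(p$depth[ipk], 0.5)   # peak below the surface
  expect_lt(p$depth[ipk], 4)
  # quasi-exponential decay beyond the peak: log-profile close to linear
  deep <- p$depth > 5 & p$depth < 15
  fit <- lm(log(p$value[deep]) ~ p$depth[deep])
  expect_lt(coef(fit)[2], -0.1)           # decaying
  expect_gt(summary(fit)$r.squared, 0.98) # close to exponential
})

test_that("capture estimators agree and boron map is zero without boron", {
  b <- water_bundle()
  expect_equal(sum(capture_rate_map(b, "b10", "collision")), 0)
  expect_equal(sum(capture_rate_map(b, "b10", "track")), 0)
  trk <- sum(capture_rate_map(b, "h_ng", "track"))
  col <- sum(capture_rate_map(b, "h_ng", "collision"))
  expect_equal(trk, col, tolerance = 0.05)
  expect_error(capture_rate_map(b, "nope"), "arg")
})

test_that("any 6LiF filter strictly decreases thermal fluence at 0.5 cm", {
  src <- fixture_source()
  rs <- run_spec(4e4, seed = 21)
  sc0 <- build_scene(NULL, phantom_material = "water")
  b0 <- run_transport(src, sc0, rs, tally_mesh(sc0, c(1, 1, 0.5)))
  v0 <- axial_profile(b0, "thermal")$value[1]
  for (f in list(filter_design("A", disc_thickness_mm = 2.5),
                 filter_design("C", disc_thickness_mm = 5,
                               square_side_cm = 8, square_thickness_mm = 5))) {
    scf <- build_scene(f, phantom_material = "water")
    bf <- run_transport(src, scf, rs, tally_mesh(scf, c(1, 1, 0.5)))
    expect_lt(axial_profile(bf, "thermal")$value[1], v0)
  }
})

test_that("unregistered material in a scene fails loudly", {
  expect_error(build_scene(NULL, phantom_material = "unobtainium"),
               "unregistered")
})
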