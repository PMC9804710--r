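# ode_counts (the RK4 production-decay oracle) lives in helper-fixtures.R
gold_lambda <- log(2) / (2.6947 * 86400)

test_that("reaction rate: trivial cases and linearity in charge", {
  sch <- data.frame(charge_mC = c(1, 2), dt_s = c(600, 600))
  m0 <- activation_measurement(0, 0.3, 0.95, gold_lambda, 100, 900, sch)
  expect_equal(reaction_rate(m0), 0)
  m1 <- activation_measurement(5000, 0.3, 0.95, gold_lambda, 100, 900, sch)
  sch2 <- sch; sch2$charge_mC <- 2 * sch$charge_mC
  m2 <- activation_measurement(5000, 0.3, 0.95, gold_lambda, 100, 900, sch2)
  expect_equal(reaction_rate(m2), reaction_rate(m1) / 2, tolerance = 1e-12)
  schz <- data.frame(charge_mC = 0, dt_s = 600)
  mz <- activation_measurement(10, 0.3, 0.95, gold_lambda, 0, 900, schz)
  expect_error(reaction_rate(mz), "zero total charge")
})

test_that("closed form matches the ODE oracle to < 0.1%", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(1:6, 1)
    Q <- runif(n, 0.1, 5)
    dt <- rep(runif(1, 60, 3600), n)
    Tc <- runif(1, 0, 1e4); Tm <- runif(1, 60, 1e4)
    C <- ode_counts(1, 0.31, 0.956, gold_lambda, Tc, Tm, Q, dt)
    m <- activation_measurement(C, 0.31, 0.956, gold_lambda, Tc, Tm,
                                data.frame(charge_mC = Q, dt_s = dt))
    expect_equal(reaction_rate(m), 1, tolerance = 1e-3)
  }
})

test_that("interval splitting is invariant in the lambda*dt -> 0 limit", {
  lam <- 1e-10  # lambda*dt ~ 1e-7
  one <- activation_measurement(1e4, 0.3, 0.95, lam, 50, 600,
                                data.frame(charge_mC = 4, dt_s = 1000))
  two <- activation_measurement(1e4, 0.3, 0.95, lam, 50, 600,
                                data.frame(charge_mC = c(2, 2),
                                           dt_s = c(500, 500)))
  expect_equal(reaction_rate(one), reaction_rate(two), tolerance = 1e-9)
})

test_that("saturation: inferred R is irradiation-length independent", {
  # forward-simulate counts at constant current for longer and longer
  # irradiations; the inferred R must not drift
  lam <- gold_lambda
  rates <- vapply(c(5, 20, 80) * 86400, function(Ttot) {
    n <- 40
    dt <- rep(Ttot / n, n); Q <- dt * 1e-3  # constant current
    C <- ode_counts(2.5, 0.3, 0.95, lam, 600, 3600, Q, dt, nstep = 500)
    m <- activation_measurement(C, 0.3, 0.95, lam, 600, 3600,
                                data.frame(charge_mC = Q, dt_s = dt))
    reaction_rate(m)
  }, 0)
  expect_rel_equal(rates, rep(2.5, 3), 1e-2)
})

test_that("cadmium difference recovers the thermal flux", {
  foil <- foil_spec()
  expect_equal(thermal_flux_cd_difference(1e-20, 1e-20, foil), 0)
  expect_equal(thermal_flux_cd_difference(2e-22, 0, foil),
               2e-22 / (foil$sigma_eff_barn * 1e-24))
  expect_error(thermal_flux_cd_difference(1e-22, 2e-22, foil),
               "negative flux")
})

test_that("predicted wire rates fold the tally pointwise", {
  b <- water_bundle()
  foil <- foil_spec()
  depths <- seq(0.5, 10, by = 0.5)
  pred <- predict_activation_profile(b, foil, depths)
  expect_true(all(pred$rate_bare >= pred$rate_cd))
  expect_equal(pred$rate_bare - pred$rate_cd, pred$rate_thermal,
               tolerance = 1e-12)
  # pointwise oracle at tally bin centres: single-voxel folding
  mesh <- b$mesh
  zc <- mesh$origin[3] + (seq_len(mesh$dims[3]) - 0.5) * mesh$d[3]
  iz <- which.min(abs(zc - 4.75))
  sig <- foil$sigma_eff_barn * 1e-24
  xc <- mesh$origin[1] + (seq_len(mesh$dims[1]) - 0.5) * mesh$d[1]
  keep <- outer(xc^2, xc^2, "+") <= 1
  want <- sig * (mean(b$onev_sub[, , iz][keep]) + mean(b$onev_epi[, , iz][keep]))
  got <- predict_activation_profile(b, foil, 4.75, radius = 1)$rate_bare
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(predict_activation_profile(b, foil, 99), "outside")
})

test_that("end-to-end: folded gold rates are consistent with the flux tally", {
  # closed loop: predict bare/covered wire rates from a transport run and
  # recover the tallied sub-cadmium 1/v-equivalent flux via the cadmium
  # difference
  b <- water_bundle()
  foil <- foil_spec()
  pred <- predict_activation_profile(b, foil, 2.25, radius = 1)
  phi <- thermal_flux_cd_difference(pred$rate_bare, pred$rate_cd, foil)
  mesh <- b$mesh
  zc <- mesh$origin[3] + (seq_len(mesh$dims[3]) - 0.5) * mesh$d[3]
  iz <- which.min(abs(zc - 2.25))
  xc <- mesh$origin[1] + (seq_len(mesh$dims[1]) - 0.5) * mesh$d[1]
  keep <- outer(xc^2, xc^2, "+") <= 1
  expect_equal(phi, mean(b$onev_sub[, , iz][keep]), tolerance = 1e-9)
})

test_that("activation CSV reader round-trips a measurement", {
  mf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  write.csv(data.frame(C = 1234, eps = 0.3, gamma = 0.95,
                       lambda = gold_lambda, Tc = 60, Tm = 1800),
            mf, row.names = FALSE)
  write.csv(data.frame(Q_mC = c(1, 2), dt_s = c(600, 600)), sf,
            row.names = FALSE)
  m <- read_activation_csv(mf, sf)
  expect_equal(m$counts, 1234)
  expect_equal(nrow(m$schedule), 2)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_activation_csv(bad, sf), "columns")
})
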