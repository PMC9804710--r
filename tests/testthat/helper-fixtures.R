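# Shared fixtures: everything is generated in code; heavy Monte Carlo runs
# are memoised so several tests can share one run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# reference desk-scale beam: bore-matched disc, defaults otherwise
fixture_source <- function() {
  memo("source", make_epithermal_source(disc_radius = 7))
}

# narrow-group (quasi mono-energetic) pencil source at energy E (eV)
mono_pencil_source <- function(E, band = "epithermal") {
  fr <- switch(band, thermal = c(1, 0, 0), epithermal = c(0, 1, 0),
               fast = c(0, 0, 1))
  make_epithermal_source(fr[1], fr[2], fr[3],
                         group_bounds = c(E * 0.995, E * 1.005),
                         thermal_cutoff_eV = if (band == "thermal") E * 1.01 else 0.5,
                         epithermal_cutoff_eV = if (band == "fast") E * 0.99 else E * 1.01,
                         disc_radius = 0.5, angular_exponent = Inf,
                         plane_z = -1, neutron_gamma_ratio = 1e12)
}

# idealized pure 1/v absorber (no scattering), Sigma_c(E0) = 0.3837 /cm
absorber_material <- function() {
  memo("absorber", {
    m <- custom_material("absorber", 1.0, A = 10, sigma0_capture = 3837,
                         sigma_scatter = 0, number_density = 1e-4,
                         channel = 1)
    register_material(m)
    m
  })
}

# analog water run shared by transport/estimator tests
water_bundle <- function() {
  memo("water_bundle", {
    src <- fixture_source()
    sc <- build_scene(NULL, phantom_material = "water")
    run_transport(src, sc, run_spec(1e5, seed = 3),
                  tally_mesh(sc, c(1, 1, 0.5)))
  })
}

# small synthetic dose-components object on an n^3 mesh
fake_components <- function(boron = 1, nitrogen = 0, hydrogen = 0, gamma = 0,
                            n = 4) {
  mesh <- list(origin = c(0, 0, 0), dims = rep(n, 3), d = rep(1, 3))
  arr <- function(v) array(v, dim = rep(n, 3))
  structure(list(boron = arr(boron), nitrogen = arr(nitrogen),
                 hydrogen = arr(hydrogen), gamma = arr(gamma),
                 mesh = mesh, strength = 1, boron_ppm = 25),
            class = "dose_components")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}

# independent activation oracle: RK4 integration of the production-decay
# equation dN/dt = R I(t) - lambda N over the pulsed schedule, exponential
# decay over the cooling time, decays counted over the live time
ode_counts <- function(R, eps, gam, lam, Tc, Tm, Q, dt, nstep = 2000) {
  N <- 0
  for (i in seq_along(Q)) {
    I <- R * Q[i] / dt[i]
    h <- dt[i] / nstep
    f <- function(n) I - lam * n
    for (k in seq_len(nstep)) {
      k1 <- f(N); k2 <- f(N + h / 2 * k1)
      k3 <- f(N + h / 2 * k2); k4 <- f(N + h * k3)
      N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  eps * gam * N * exp(-lam * Tc) * (1 - exp(-lam * Tm))
}
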