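test_that("spectrum construction validates and normalizes", {
  s <- energy_spectrum(c(1, 10, 100), c(2, 2))
  expect_equal(sum(s$group_intensity), 1, tolerance = 1e-12)
  expect_error(energy_spectrum(c(1), numeric(0)), "empty")
  expect_error(energy_spectrum(c(10, 1), 1), "ascending")
  expect_error(energy_spectrum(c(1, 10), -1), "non-negative")
  expect_error(make_epithermal_source(0.5, 0.5, 0.1), "sum to 1")
})

test_that("pure 1/E case gives log-ratio group intensities", {
  b <- c(0.5, 5, 50, 500, 1e4)
  src <- make_epithermal_source(0, 1, 0, group_bounds = b)
  expect_equal(src$neutron_spectrum$group_intensity,
               log(b[-1] / b[-5]) / log(b[5] / b[1]), tolerance = 1e-12)
})

test_that("pure thermal case puts all intensity below the cadmium cutoff", {
  src <- make_epithermal_source(1, 0, 0)
  bnd <- src$neutron_spectrum$group_bounds
  above <- bnd[-length(bnd)] >= 0.5  # groups entirely above the cutoff
  expect_true(all(src$neutron_spectrum$group_intensity[above] < 1e-12))
})

test_that("default spectrum matches numerical quadrature of the shape", {
  src <- make_epithermal_source()
  b <- src$neutron_spectrum$group_bounds
  kT <- 0.0253; Tf <- 1.2e4
  shape <- function(E) {
    v <- numeric(length(E))
    th <- E < 0.5; ep <- E >= 0.5 & E < 1e4; fa <- E >= 1e4
    th_tot <- integrate(function(x) x * exp(-x / kT), 1e-3, 0.5,
                        rel.tol = 1e-10)$value
    fa_tot <- integrate(function(x) x * exp(-x / Tf), 1e4, 3e7,
                        rel.tol = 1e-10)$value
    v[th] <- 0.02 * E[th] * exp(-E[th] / kT) / th_tot
    v[ep] <- 0.88 / E[ep] / log(1e4 / 0.5)
    v[fa] <- 0.10 * E[fa] * exp(-E[fa] / Tf) / fa_tot
    v
  }
  want <- vapply(seq_len(length(b) - 1), function(i)
    integrate(shape, b[i], b[i + 1], rel.tol = 1e-9,
              subdivisions = 400L)$value, 0)
  expect_rel_equal(src$neutron_spectrum$group_intensity[want > 1e-12],
                   want[want > 1e-12], 1e-6)
})

test_that("source sampling honors the stated laws", {
  src <- fixture_source()
  p <- sample_source_particles(src, 1e5, seed = 2)
  n <- p[p$species == "neutron", ]
  # cosine-law moment for m = 2: E[mu] = (m+1)/(m+2)
  se <- sd(n$uz) / sqrt(nrow(n))
  expect_lt(abs(mean(n$uz) - 3 / 4), 3 * se)
  # uniform disc: P(r < R/sqrt(2)) = 1/2
  r <- sqrt(n$x^2 + n$y^2)
  ph <- mean(r < 7 / sqrt(2))
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / nrow(n)))
  # group frequencies: chi-square goodness of fit
  sp <- src$neutron_spectrum
  g <- cut(n$energy, sp$group_bounds, labels = FALSE)
  obs <- tabulate(g, nbins = length(sp$group_intensity))
  keep <- sp$group_intensity * nrow(n) > 5
  chi <- sum((obs[keep] - nrow(n) * sp$group_intensity[keep])^2 /
               (nrow(n) * sp$group_intensity[keep]))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("m = 1 cosine law and the pencil-beam limit", {
  src <- make_epithermal_source(disc_radius = 7, angular_exponent = 1)
  p <- sample_source_particles(src, 1e5, seed = 4)
  n <- p[p$species == "neutron", ]
  expect_lt(abs(mean(n$uz) - 2 / 3), 3 * sd(n$uz) / sqrt(nrow(n)))
  pencil <- make_epithermal_source(disc_radius = 7, angular_exponent = Inf)
  q <- sample_source_particles(pencil, 100, seed = 1)
  expect_true(all(q$uz == 1))
})

test_that("same seed gives a bitwise-identical particle stream", {
  src <- fixture_source()
  a <- sample_source_particles(src, 1000, seed = 9)
  b <- sample_source_particles(src, 1000, seed = 9)
  expect_identical(a, b)
  c <- sample_source_particles(src, 1000, seed = 10)
  expect_false(identical(a$energy, c$energy))
})

test_that("spectrum text files round-trip exactly", {
  src <- fixture_source()
  f <- tempfile(fileext = ".txt")
  write_spectrum(src$neutron_spectrum, f)
  back <- read_spectrum(f)
  expect_identical(back$group_bounds, src$neutron_spectrum$group_bounds)
  expect_identical(back$group_intensity, src$neutron_spectrum$group_intensity)
})
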