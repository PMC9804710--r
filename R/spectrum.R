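#' Grouped emission spectrum
#'
#' A multigroup emission spectrum: strictly ascending positive group bounds
#' (eV) and non-negative per-group relative intensities, normalized to sum
#' to one.
#'
#' @param group_bounds Numeric vector, length G+1, strictly ascending, > 0 (eV).
#' @param group_intensity Numeric vector, length G, >= 0, not all zero.
#' @return An `energy_spectrum` object.
#' @export
energy_spectrum <- function(group_bounds, group_intensity) {
  group_bounds <- as.numeric(group_bounds)
  group_intensity <- as.numeric(group_intensity)
  if (length(group_bounds) < 2L)
    stop("empty group structure: need at least one group")
  if (length(group_intensity) != length(group_bounds) - 1L)
    stop("group_intensity must have length(group_bounds) - 1 entries")
  if (any(!is.finite(group_bounds)) || any(group_bounds <= 0))
    stop("group bounds must be finite and positive")
  if (any(diff(group_bounds) <= 0))
    stop("group bounds must be strictly ascending")
  if (any(group_intensity < 0))
    stop("group intensities must be non-negative")
  s <- sum(group_intensity)
  if (s <= 0) stop("group intensities sum to zero")
  # skip renormalization of an already-normalized vector so that text
  # round-trips are bit-exact
  if (abs(s - 1) > 1e-12) group_intensity <- group_intensity / s
  structure(
    list(group_bounds = group_bounds, group_intensity = group_intensity),
    class = "energy_spectrum"
  )
}

#' @export
print.energy_spectrum <- function(x, ...) {
  g <- length(x$group_intensity)
  cat(sprintf("<energy_spectrum> %d groups, %.3g eV .. %.3g eV\n",
              g, x$group_bounds[1], x$group_bounds[g + 1]))
  invisible(x)
}

# closed-form band integrals of the three analytic shapes -------------------

# integral of E*exp(-E/kT) dE over [a, b] (Maxwellian flux shape)
maxwellian_integral <- function(a, b, kT) {
  f <- function(x) -kT * (x + kT) * exp(-x / kT)
  f(b) - f(a)
}

# integral of 1/E dE over [a, b]
one_over_e_integral <- function(a, b) log(b / a)

#' Synthetic epithermal source model
#'
#' Builds the parametric stand-in for a beam-shaping-assembly exit spectrum:
#' a Maxwellian thermal component below the cadmium cutoff, a 1/E epithermal
#' component between the cutoff and the upper epithermal bound, and an
#' evaporation-like (Maxwellian, hot temperature) fast tail above it, plus a
#' gamma contaminant line spectrum, emitted from a planar disc with a
#' cos^m(theta) angular law.
#'
#' The per-group neutron intensities are the closed-form integrals of the
#' analytic shape over each group, so the grouped spectrum converges to the
#' analytic one under refinement.
#'
#' @param thermal_fraction,epithermal_fraction,fast_fraction Band weights;
#'   must be non-negative and sum to 1 within 1e-9.
#' @param group_bounds Energy group bounds in eV (default: 40 log-spaced
#'   groups spanning 1e-3 eV to 30 MeV).
#' @param gamma_params Two-column data.frame (`energy_eV`, `intensity`)
#'   of contaminant gamma lines; each line becomes a narrow group.
#' @param disc_radius Source disc radius, cm.  Full-scale clinical
#'   geometries use 150 cm (the default); desk-scale run configs typically
#'   override this with a bore-matched disc (see the methods vignette).
#' @param angular_exponent m in the cos^m emission law (>= 0); `Inf` gives
#'   the pencil-beam limit.
#' @param plane_z Source plane position on the beam axis, cm (beam travels +z,
#'   phantom entry face at z = 0).
#' @param strength Source particles per second per mA (arbitrary reference
#'   scale in synthetic mode).
#' @param neutron_gamma_ratio Neutron-to-gamma source particle ratio.
#' @param thermal_cutoff_eV,epithermal_cutoff_eV Band boundaries (cadmium
#'   cutoff 0.5 eV; upper epithermal 10 keV).
#' @param thermal_kT_eV Maxwellian temperature of the thermal component, eV.
#' @param fast_T_eV Evaporation temperature of the fast tail, eV.
#' @return A `source_model` object.
#' @export
make_epithermal_source <- function(thermal_fraction = 0.02,
                                   epithermal_fraction = 0.88,
                                   fast_fraction = 0.10,
                                   group_bounds = NULL,
                                   gamma_params = NULL,
                                   disc_radius = 150,
                                   angular_exponent = 2,
                                   plane_z = -8,
                                   strength = 2e11,
                                   neutron_gamma_ratio = 100,
                                   thermal_cutoff_eV = THERMAL_CUT_EV,
                                   epithermal_cutoff_eV = EPI_CUT_EV,
                                   thermal_kT_eV = 0.0253,
                                   fast_T_eV = 1.2e4) {
  fr <- c(thermal_fraction, epithermal_fraction, fast_fraction)
  if (any(fr < 0)) stop("band fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("band fractions must sum to 1 within 1e-9")
  if (is.null(group_bounds))
    group_bounds <- 10^seq(log10(1e-3), log10(3e7), length.out = 41)
  group_bounds <- as.numeric(group_bounds)
  if (length(group_bounds) < 2L) stop("empty group structure")
  if (any(diff(group_bounds) <= 0) || any(group_bounds <= 0))
    stop("invalid group bounds")
  if (disc_radius <= 0) stop("disc_radius must be > 0")
  if (!is.infinite(angular_exponent) && angular_exponent < 0)
    stop("angular_exponent must be >= 0")
  if (strength <= 0) stop("strength must be > 0")

  emin <- group_bounds[1]
  emax <- group_bounds[length(group_bounds)]
  # band totals of each shape (for normalizing shapes within their band)
  th_lo <- emin
  th_hi <- min(thermal_cutoff_eV, emax)
  ep_lo <- max(thermal_cutoff_eV, emin)
  ep_hi <- min(epithermal_cutoff_eV, emax)
  fa_lo <- max(epithermal_cutoff_eV, emin)
  fa_hi <- emax
  th_tot <- if (th_hi > th_lo) maxwellian_integral(th_lo, th_hi, thermal_kT_eV) else 0
  ep_tot <- if (ep_hi > ep_lo) one_over_e_integral(ep_lo, ep_hi) else 0
  fa_tot <- if (fa_hi > fa_lo) maxwellian_integral(fa_lo, fa_hi, fast_T_eV) else 0
  for (i in 1:3) {
    tot <- c(th_tot, ep_tot, fa_tot)[i]
    if (fr[i] > 0 && tot <= 0)
      stop("band with non-zero fraction lies outside the group structure")
  }

  g <- length(group_bounds) - 1L
  intens <- numeric(g)
  for (i in seq_len(g)) {
    a <- group_bounds[i]
    b <- group_bounds[i + 1]
    v <- 0
    aa <- max(a, th_lo); bb <- min(b, th_hi)
    if (fr[1] > 0 && bb > aa)
      v <- v + fr[1] * maxwellian_integral(aa, bb, thermal_kT_eV) / th_tot
    aa <- max(a, ep_lo); bb <- min(b, ep_hi)
    if (fr[2] > 0 && bb > aa)
      v <- v + fr[2] * one_over_e_integral(aa, bb) / ep_tot
    aa <- max(a, fa_lo); bb <- min(b, fa_hi)
    if (fr[3] > 0 && bb > aa)
      v <- v + fr[3] * maxwellian_integral(aa, bb, fast_T_eV) / fa_tot
    intens[i] <- v
  }
  nspec <- energy_spectrum(group_bounds, intens)

  if (is.null(gamma_params))
    gamma_params <- data.frame(energy_eV = c(4.78e5, 2.223e6),
                               intensity = c(0.4, 0.6))
  gb <- numeric(0); gi <- numeric(0)
  o <- order(gamma_params$energy_eV)
  for (k in o) {
    e <- gamma_params$energy_eV[k]
    gb <- c(gb, e * 0.999, e * 1.001)
    gi <- c(gi, gamma_params$intensity[k])
  }
  # line groups are disjoint narrow bins; stitch into one bound vector with
  # zero-intensity gaps
  bounds <- gb[1]
  ints <- numeric(0)
  for (k in seq_along(gi)) {
    lo <- gb[2 * k - 1]; hi <- gb[2 * k]
    if (lo > bounds[length(bounds)]) {
      bounds <- c(bounds, lo)
      ints <- c(ints, 0)
    }
    bounds <- c(bounds, hi)
    ints <- c(ints, gi[k])
  }
  gspec <- energy_spectrum(bounds, ints)

  structure(
    list(neutron_spectrum = nspec, gamma_spectrum = gspec,
         disc_radius = disc_radius, plane_z = plane_z,
         angular_exponent = angular_exponent, strength = strength,
         neutron_gamma_ratio = neutron_gamma_ratio,
         bands = c(thermal = thermal_fraction, epithermal = epithermal_fraction,
                   fast = fast_fraction),
         thermal_kT_eV = thermal_kT_eV, fast_T_eV = fast_T_eV,
         thermal_cutoff_eV = thermal_cutoff_eV,
         epithermal_cutoff_eV = epithermal_cutoff_eV),
    class = "source_model"
  )
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf(paste0("<source_model> disc r=%.3g cm at z=%.3g cm, cos^%s law\n",
                     "  bands (th/epi/fast): %.3g/%.3g/%.3g, ",
                     "strength %.3g /s/mA, n:g = %g:1\n"),
              x$disc_radius, x$plane_z,
              if (is.infinite(x$angular_exponent)) "Inf (pencil)"
              else format(x$angular_exponent),
              x$bands[1], x$bands[2], x$bands[3],
              x$strength, x$neutron_gamma_ratio))
  invisible(x)
}

# internal: source_model -> list consumed by the C++ kernel
as_cpp_source <- function(source) {
  m <- source$angular_exponent
  list(
    n_bounds = source$neutron_spectrum$group_bounds,
    n_int = source$neutron_spectrum$group_intensity,
    g_bounds = source$gamma_spectrum$group_bounds,
    g_int = source$gamma_spectrum$group_intensity,
    radius = source$disc_radius,
    z0 = source$plane_z,
    m = if (is.infinite(m)) -1 else m,
    p_gamma = 1 / (1 + source$neutron_gamma_ratio)
  )
}

#' Sample source particles
#'
#' Draws particle states from a source model: position uniform over the disc,
#' direction from the cos^m law about +z, energy uniform in lethargy within
#' the sampled group, species by the configured neutron:gamma ratio.  The
#' stream is deterministic given the seed.
#'
#' @param source A `source_model`.
#' @param n Number of particles.
#' @param seed Integer seed.
#' @return data.frame with columns species ("neutron"/"photon"), x, y, z,
#'   ux, uy, uz, energy (eV), weight.
#' @export
sample_source_particles <- function(source, n, seed = 1L) {
  stopifnot(inherits(source, "source_model"), n >= 1)
  m <- cpp_sample_source(as_cpp_source(source), as.integer(n), as.numeric(seed))
  out <- as.data.frame(m)
  out$species <- ifelse(out$species == 1, "photon", "neutron")
  out$weight <- 1.0
  out
}

#' Write / read a spectrum as two-column text
#'
#' Plain whitespace-separated text with `#` comments: first data row is the
#' lowest group bound (intensity field 0), subsequent rows are group upper
#' bounds with the group's relative intensity.  Full double precision, so
#' write/read round-trips exactly.
#'
#' @param spectrum An `energy_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  b <- spectrum$group_bounds
  i <- spectrum$group_intensity
  lines <- c("# beamlab spectrum: bound_eV intensity",
             "# first row = lowest bound (intensity 0)",
             sprintf("%.17g %.17g", b, c(0, i)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  parts <- strsplit(trimws(raw), "[[:space:],]+")
  m <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (any(!is.finite(m))) stop("malformed spectrum file: non-numeric field")
  energy_spectrum(m[, 1], m[-1, 2])
}
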