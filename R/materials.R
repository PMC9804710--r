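#' Nuclide lookup
#'
#' Returns the point-constant record of a nuclide from the constants file:
#' atomic mass (amu), 2200 m/s capture cross section (barns), free-atom
#' scattering cross section (barns), capture reaction descriptor and the
#' 1/v flag.
#'
#' @param name Nuclide key, e.g. "Li6", "B10", "H1", "N14", "Au197".
#' @return A `nuclide` object.
#' @export
nuclide <- function(name) {
  nd <- nuclear_constants()$nuclides[[name]]
  if (is.null(nd)) stop("unknown nuclide: ", name)
  structure(c(list(name = name), nd), class = "nuclide")
}

#' 1/v capture cross section
#'
#' sigma(E) = sigma0 * sqrt(E0 / E) with E0 = 0.0253 eV (2200 m/s anchor).
#'
#' @param nuc A `nuclide` (or nuclide name).
#' @param energy Neutron energy in eV (> 0), vectorized.
#' @return Cross section in barns.
#' @export
sigma_capture <- function(nuc, energy) {
  if (is.character(nuc)) nuc <- nuclide(nuc)
  if (!isTRUE(nuc$has_1v_capture))
    stop("unsupported channel: ", nuc$name, " has no 1/v capture")
  if (any(energy <= 0)) stop("energy must be > 0")
  nuc$sigma0_capture * sqrt(E0_EV / energy)
}

new_material <- function(name, density, number_densities, elem_mass_fractions) {
  k <- nuclear_constants()
  nucs <- names(number_densities)
  A <- vapply(nucs, function(n) k$nuclides[[n]]$atomic_mass, 0)
  s0 <- vapply(nucs, function(n) k$nuclides[[n]]$sigma0_capture, 0)
  ss <- vapply(nucs, function(n) k$nuclides[[n]]$sigma_scatter, 0)
  chan <- vapply(nucs, function(n) {
    ch <- k$nuclides[[n]]$channel
    switch(ch, "B10_NA" = 1L, "LI6_NA" = 2L, "N14_NP" = 3L, "H_NG" = 4L, 0L)
  }, 0L)
  # photon mu_en (cm^-1 at nominal density) from elemental mass coefficients
  mt <- k$mu_en_over_rho
  muE <- mt$energy_MeV
  mu <- rep(0, length(muE))
  for (el in names(elem_mass_fractions)) {
    co <- mt[[el]]
    if (is.null(co)) co <- mt[["P"]]  # minor-element fallback
    mu <- mu + elem_mass_fractions[[el]] * co
  }
  mu <- mu * density
  structure(
    list(name = name, density = density,
         number_densities = number_densities,       # atoms / (barn cm)
         elem_mass_fractions = elem_mass_fractions,
         A = unname(A), s0 = unname(s0), ss = unname(ss), chan = unname(chan),
         muenE = muE, muen = mu),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s, rho = %.4g g/cm^3, %d nuclides\n",
              x$name, x$density, length(x$number_densities)))
  invisible(x)
}

#' Build a material from mass fractions
#'
#' Number densities follow the Avogadro relation
#' N_i = w_i * rho * N_A / M_i (expressed in atoms per barn cm).  Elements
#' expand to their constituent nuclides per the constants file; zero-mass
#' components are dropped.
#'
#' @param name Material name.
#' @param density g/cm^3 (> 0).
#' @param mass_fractions Named numeric vector (element symbols); must sum
#'   to 1 within 1e-6.
#' @return A `material`.
#' @export
build_material <- function(name, density, mass_fractions) {
  if (density <= 0) stop("density must be > 0")
  if (abs(sum(mass_fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1")
  k <- nuclear_constants()
  NA_ <- k$meta$avogadro
  nd <- numeric(0)
  mass_fractions <- mass_fractions[mass_fractions > 0]
  for (el in names(mass_fractions)) {
    ed <- k$elements[[el]]
    if (is.null(ed)) stop("unknown element: ", el)
    n_el <- mass_fractions[[el]] * density * NA_ / ed$molar_mass * 1e-24
    for (nuc in names(ed$nuclides)) {
      add <- n_el * ed$nuclides[[nuc]]
      nd[nuc] <- (if (is.na(nd[nuc])) 0 else nd[nuc]) + add
    }
  }
  new_material(name, density, nd, as.list(mass_fractions))
}

#' Lithium fluoride with variable 6Li enrichment
#'
#' @param enrichment 6Li atom fraction of the lithium (natural = 0.0759).
#' @param density g/cm^3 (sintered LiF default 2.635).
#' @param name Optional material name.
#' @return A `material`.
#' @export
lif_material <- function(enrichment = 0.99, density = NULL, name = NULL) {
  k <- nuclear_constants()
  if (is.null(density)) density <- k$lif_density
  if (enrichment < 0 || enrichment > 1) stop("enrichment must be in [0, 1]")
  m6 <- k$nuclides$Li6$atomic_mass
  m7 <- k$nuclides$Li7$atomic_mass
  mF <- k$elements$F$molar_mass
  mLi <- enrichment * m6 + (1 - enrichment) * m7
  M <- mLi + mF
  NA_ <- k$meta$avogadro
  n_lif <- density * NA_ / M * 1e-24  # formula units / (barn cm)
  nd <- c(Li6 = enrichment * n_lif, Li7 = (1 - enrichment) * n_lif, F19 = n_lif)
  nd <- nd[nd > 0]
  fr_li <- mLi / M
  if (is.null(name)) name <- sprintf("lif_e%02.0f", 100 * enrichment)
  new_material(name, density, nd,
               list(Li = fr_li, F = mF / M))
}

#' Mix registered materials by mass
#'
#' Volume-additive mixing: the mixture density is 1 / sum(w_i / rho_i) and
#' nuclide number densities combine with the corresponding volume fractions.
#'
#' @param components Named list material -> mass fraction (sum to 1).
#' @param name Mixture name.
#' @return A `material`.
#' @export
mix_materials <- function(components, name = "mixture") {
  w <- vapply(components, function(x) x$mass, 0)
  mats <- lapply(components, function(x) x$material)
  if (abs(sum(w) - 1) > 1e-6) stop("mass fractions must sum to 1")
  rho <- 1 / sum(w / vapply(mats, function(m) m$density, 0))
  nd <- numeric(0)
  ef <- list()
  for (i in seq_along(mats)) {
    phi <- w[i] * rho / mats[[i]]$density  # volume fraction
    for (nuc in names(mats[[i]]$number_densities))
      nd[nuc] <- (if (is.na(nd[nuc])) 0 else nd[nuc]) +
        phi * mats[[i]]$number_densities[[nuc]]
    for (el in names(mats[[i]]$elem_mass_fractions))
      ef[[el]] <- (if (is.null(ef[[el]])) 0 else ef[[el]]) +
        w[i] * mats[[i]]$elem_mass_fractions[[el]]
  }
  new_material(name, rho, nd, ef)
}

#' Material registry
#'
#' All materials of the beam model, addressable by name: phantom media
#' (water, PMMA, ICRP brain, soft tissue, skin), structural media (air,
#' polyethylene, cortical bone, lung, adipose), and the filter media -
#' LiF at 99% 6Li enrichment (the simulated design), natural LiF, the
#' as-built ~60/40 enriched/natural sinter mixture, and the LiF-loaded
#' polyethylene collimator (50/50 by mass).
#'
#' @return Named list of `material` objects (cached).
#' @export
material_registry <- function() {
  if (!is.null(.beamlab$registry)) return(.beamlab$registry)
  k <- nuclear_constants()
  reg <- list()
  for (nm in names(k$materials)) {
    mm <- k$materials[[nm]]
    reg[[nm]] <- build_material(nm, mm$density, unlist(mm$mass_fractions))
  }
  nat <- k$li6_natural_atom_fraction
  reg$lif_enriched <- lif_material(0.99, name = "lif_enriched")
  reg$lif_natural <- lif_material(nat, name = "lif_natural")
  reg$lif_asbuilt <- mix_materials(
    list(a = list(material = reg$lif_enriched, mass = 0.6),
         b = list(material = reg$lif_natural, mass = 0.4)),
    name = "lif_asbuilt")
  reg$lif_polyethylene <- mix_materials(
    list(a = list(material = reg$lif_natural, mass = 0.5),
         b = list(material = reg$polyethylene, mass = 0.5)),
    name = "lif_polyethylene")
  # true void (zero cross sections) for idealized validation scenes
  reg$void <- custom_material("void", 1e-9, A = 1, sigma0_capture = 0,
                              sigma_scatter = 0, number_density = 0)
  .beamlab$registry <- reg
  reg
}

#' @rdname material_registry
#' @param name Material name.
#' @export
get_material <- function(name) {
  m <- material_registry()[[name]]
  if (is.null(m)) stop("unregistered material: ", name)
  m
}

#' Define a material from explicit nuclide constants
#'
#' Bypasses the constants file: direct per-nuclide atomic masses, 2200 m/s
#' capture and scattering cross sections and number densities.  Intended for
#' idealized media (pure absorbers, single-nuclide slabs) in validation
#' studies.
#'
#' @param name Material name.
#' @param density g/cm^3.
#' @param A Atomic masses, amu.
#' @param sigma0_capture,sigma_scatter Cross sections, barns.
#' @param number_density Atoms per barn cm (same length).
#' @param channel Capture channel codes (0 none, 1 B10, 2 Li6, 3 N14,
#'   4 H(n,g)).
#' @param nuclide_names Optional names for the number-density vector.
#' @return A `material`.
#' @export
custom_material <- function(name, density, A, sigma0_capture, sigma_scatter,
                            number_density, channel = 0,
                            nuclide_names = NULL) {
  n <- length(A)
  channel <- rep(channel, length.out = n)
  if (is.null(nuclide_names)) nuclide_names <- paste0("nuc", seq_len(n))
  nd <- as.numeric(number_density)
  names(nd) <- nuclide_names
  structure(
    list(name = name, density = density, number_densities = nd,
         elem_mass_fractions = list(),
         A = as.numeric(A), s0 = as.numeric(sigma0_capture),
         ss = as.numeric(sigma_scatter), chan = as.integer(channel),
         muenE = c(1), muen = c(0)),
    class = "material")
}

#' @rdname custom_material
#' @param material A `material` to add to the registry under its name.
#' @export
register_material <- function(material) {
  stopifnot(inherits(material, "material"))
  reg <- material_registry()
  reg[[material$name]] <- material
  .beamlab$registry <- reg
  invisible(material)
}

#' Macroscopic cross sections
#'
#' Sums N_i * sigma_i over the material's nuclides: capture by the 1/v law,
#' scattering energy-independent.  Returns per-cm totals.
#'
#' @param material A `material` or registered name.
#' @param energy Neutron energy, eV (vectorized).
#' @return data.frame with columns capture, scatter, total (cm^-1).
#' @export
macroscopic_xs <- function(material, energy) {
  if (is.character(material)) material <- get_material(material)
  if (any(energy <= 0)) stop("energy must be > 0")
  N <- unlist(material$number_densities)
  cap <- sum(N * material$s0) * sqrt(E0_EV / energy)
  sct <- rep(sum(N * material$ss), length(energy))
  data.frame(capture = cap, scatter = sct, total = cap + sct)
}

# internal: material -> list consumed by the C++ kernel
as_cpp_material <- function(m) {
  list(A = m$A, s0 = m$s0, ss = m$ss,
       N = unname(unlist(m$number_densities)),
       chan = as.integer(m$chan), density = m$density,
       muenE = m$muenE, muen = m$muen)
}
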