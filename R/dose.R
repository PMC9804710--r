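#' Biological weighting configuration
#'
#' RBE factors for the nitrogen, hydrogen and gamma dose components, CBE
#' factors for the boron component per tissue role, boron concentrations and
#' the healthy-brain dose limit.  Defaults are the standard clinical set:
#' RBE 3.0/3.0/1.0, CBE 3.8 (tumor) / 2.5 (skin) / 1.34 (normal brain),
#' 25 ug/g blood boron with a 3.5x tumor-to-blood ratio and a skin ratio of
#' 1.0, and a 12.5 Gy maximum biologically weighted brain dose.
#'
#' @param ... Overrides of any field.
#' @return A `weighting_config`.
#' @export
weighting_config <- function(...) {
  cfg <- list(rbe_nitrogen = 3.0, rbe_hydrogen = 3.0, rbe_gamma = 1.0,
              cbe_tumor = 3.8, cbe_skin = 2.5, cbe_normal = 1.34,
              blood_boron = 25, tumor_to_blood = 3.5, skin_to_blood = 1.0,
              brain_dose_limit = 12.5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown weighting fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (any(unlist(cfg) <= 0)) stop("all weighting parameters must be positive")
  structure(cfg, class = "weighting_config")
}

#' @rdname weighting_config
#' @param path JSON file with weighting fields.
#' @export
read_weighting_config <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  do.call(weighting_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname weighting_config
#' @param config A `weighting_config` to serialize.
#' @export
write_weighting_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Four-component physical dose rates
#'
#' Converts the transport tallies into the four KERMA-approximation absorbed
#' dose-rate maps, Gy/h at the reference source strength (1 mA):
#' \itemize{
#'   \item boron: 10B capture rate (1/v-folded track-length tally times the
#'     local 10B number density at `boron_ppm` of 10B per gram of tissue)
#'     times the 2.31 MeV branch-weighted local charged-particle energy;
#'   \item nitrogen: 14N(n,p) rate times 0.626 MeV, using the material's own
#'     nitrogen content;
#'   \item hydrogen: elastic-recoil energy transfer to hydrogen above the
#'     thermal cutoff (fast-neutron dose);
#'   \item gamma: photon energy absorption.
#' }
#'
#' @param bundle A `tally_bundle`.
#' @param boron_ppm 10B concentration in ug per g of tissue: scalar or a
#'   per-voxel map.  Applied only where the medium has tissue-like density
#'   (> 0.05 g/cm^3).
#' @param strength Source particles per second per mA; defaults to the
#'   source model's value recorded in the bundle.
#' @return A `dose_components` object (boron/nitrogen/hydrogen/gamma arrays).
#' @export
compute_dose_components <- function(bundle, boron_ppm = 25, strength = NULL) {
  stopifnot(inherits(bundle, "tally_bundle"))
  if (is.null(strength)) strength <- bundle$source_strength
  k <- nuclear_constants()
  dims <- dim(bundle$onev_sub)
  if (!is.null(dim(boron_ppm)) && !all(dim(boron_ppm) == dims))
    stop("boron_ppm map shape does not match the tally mesh")
  rho <- bundle$dens
  tissue <- rho > 0.05
  conv <- MEV_PER_G_TO_GY * strength * 3600  # (MeV/cm^3/src) -> Gy/h, via /rho
  safe_rho <- ifelse(rho > 1e-6, rho, 1)

  # boron: N_B [atoms/(b cm)] = ppm*1e-6 * rho * N_A / M(B10) * 1e-24;
  # fold with the per-unit-N tally, so rho cancels against the per-mass dose
  NA_ <- k$meta$avogadro
  MB <- k$nuclides$B10$atomic_mass
  nb_per_rho <- boron_ppm * 1e-6 * NA_ / MB * 1e-24   # per (b cm) per (g/cm^3)
  QB <- k$kerma_constants_MeV$B10_NA
  boron <- bundle$b10_fold * nb_per_rho * QB * conv
  boron <- boron * tissue

  MN <- k$nuclides$N14$atomic_mass
  QN <- k$kerma_constants_MeV$N14_NP
  # material nitrogen number density per unit mass density
  wN <- vapply(bundle$materials, function(nm) {
    f <- get_material(nm)$elem_mass_fractions[["N"]]
    if (is.null(f)) 0 else f
  }, 0)
  nN_per_rho <- array(wN[bundle$matidx], dim = dims) * NA_ / MN * 1e-24
  nitrogen <- bundle$n14_fold * nN_per_rho * QN * conv

  hydrogen <- bundle$h_kerma / safe_rho * conv
  gamma <- bundle$photon$edep / safe_rho * conv

  structure(list(boron = boron, nitrogen = nitrogen, hydrogen = hydrogen,
                 gamma = gamma, mesh = bundle$mesh, strength = strength,
                 boron_ppm = boron_ppm),
            class = "dose_components")
}

#' @export
print.dose_components <- function(x, ...) {
  cat(sprintf(paste0("<dose_components> Gy/h at %.3g src/s/mA; max ",
                     "B=%.3g N=%.3g H=%.3g G=%.3g\n"), x$strength,
              max(x$boron), max(x$nitrogen), max(x$hydrogen), max(x$gamma)))
  invisible(x)
}

#' Total physical dose rate
#' @param components A `dose_components`.
#' @return 3-d array, Gy/h.
#' @export
total_dose <- function(components) {
  components$boron + components$nitrogen + components$hydrogen +
    components$gamma
}

role_boron_factor <- function(config, role) {
  switch(role,
         tumor = config$tumor_to_blood,
         skin = config$skin_to_blood,
         normal = 1.0,
         stop("unknown role: ", role))
}

role_cbe <- function(config, role) {
  switch(role,
         tumor = config$cbe_tumor,
         skin = config$cbe_skin,
         normal = config$cbe_normal,
         stop("unknown role: ", role))
}

#' Biologically weighted dose rate
#'
#' W = rbe_gamma * D_gamma + rbe_nitrogen * D_N + rbe_hydrogen * D_H +
#' CBE(role) * D_B.  The components are taken as given, i.e. the boron
#' component must already be at the role's boron concentration (blood
#' concentration times the role's boron ratio); [role_dose_map()] handles
#' that rescaling from blood-concentration components.
#'
#' @param components A `dose_components` at the role's boron concentration.
#' @param config A [weighting_config()].
#' @param role "tumor", "normal" or "skin".
#' @return A `weighted_dose_map` (array with mesh/role attributes).
#' @export
weight_dose <- function(components, config = weighting_config(),
                        role = c("normal", "tumor", "skin")) {
  role <- match.arg(role)
  w <- config$rbe_gamma * components$gamma +
    config$rbe_nitrogen * components$nitrogen +
    config$rbe_hydrogen * components$hydrogen +
    role_cbe(config, role) * components$boron
  structure(w, mesh = components$mesh, role = role,
            class = c("weighted_dose_map", class(w)))
}

#' @rdname weight_dose
#' @param components_blood A `dose_components` computed at blood boron
#'   concentration; the boron component is rescaled by the role's
#'   tumor/skin-to-blood ratio before weighting.
#' @export
role_dose_map <- function(components_blood, config = weighting_config(),
                          role = c("normal", "tumor", "skin")) {
  role <- match.arg(role)
  comp <- components_blood
  comp$boron <- comp$boron * role_boron_factor(config, role)
  weight_dose(comp, config, role)
}

#' Tumor / normal-tissue axial dose constructs
#'
#' The standard beam-evaluation construct: the biologically weighted dose
#' rate along the central axis computed everywhere as if the voxel were tumor
#' (boron at tumor-to-blood times blood concentration, tumor CBE) and as
#' normal tissue (blood concentration, normal CBE).
#'
#' @param components A `dose_components` at blood boron.
#' @param config A [weighting_config()].
#' @param radius Axial averaging column radius, cm.
#' @return list(tumor = depth_profile, normal = depth_profile).
#' @export
tumor_dose_profile <- function(components, config = weighting_config(),
                               radius = 1.0) {
  t_map <- role_dose_map(components, config, "tumor")
  n_map <- role_dose_map(components, config, "normal")
  mesh <- components$mesh
  list(tumor = depth_profile(mesh_centers(mesh, 3),
                             axial_average(t_map, mesh, radius)),
       normal = depth_profile(mesh_centers(mesh, 3),
                              axial_average(n_map, mesh, radius)))
}

#' Per-component axial profiles
#'
#' @param components A `dose_components`.
#' @param radius Averaging column radius, cm.
#' @return data.frame(depth, boron, nitrogen, hydrogen, gamma, total).
#' @export
component_profiles <- function(components, radius = 1.0) {
  mesh <- components$mesh
  data.frame(
    depth = mesh_centers(mesh, 3),
    boron = axial_average(components$boron, mesh, radius),
    nitrogen = axial_average(components$nitrogen, mesh, radius),
    hydrogen = axial_average(components$hydrogen, mesh, radius),
    gamma = axial_average(components$gamma, mesh, radius),
    total = axial_average(total_dose(components), mesh, radius))
}
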