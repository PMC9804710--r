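#' Advantage depth
#'
#' The depth where the biologically weighted tumor dose falls to the peak
#' weighted normal-tissue dose: linear interpolation of the deepest crossing
#' of tumor(z) with max_z NT(z).  The deepest crossing resolves shallow
#' build-up regions that cross the level more than once, since AD is a
#' penetration measure.
#'
#' @param tumor_profile,nt_profile `depth_profile`s on a common depth grid.
#' @param skin_depth_cm NT-peak search excludes depths shallower than this
#'   (the skin band is scored separately; default one 2-mm voxel layer).
#' @return Depth in cm.  `NA` with attribute `status = "undefined"` if the
#'   tumor profile never exceeds the NT peak; the deepest grid point with
#'   `status = "beyond-grid"` if it never falls below it.
#' @export
advantage_depth <- function(tumor_profile, nt_profile, skin_depth_cm = 0.2) {
  stopifnot(inherits(tumor_profile, "depth_profile"),
            inherits(nt_profile, "depth_profile"),
            isTRUE(all.equal(tumor_profile$depth, nt_profile$depth)))
  z <- tumor_profile$depth
  tv <- tumor_profile$value
  keep <- nt_profile$depth >= skin_depth_cm
  peak <- max(nt_profile$value[keep])
  if (max(tv) < peak) {
    return(structure(NA_real_, status = "undefined"))
  }
  above <- tv >= peak
  i_last <- max(which(above))
  if (i_last == length(z)) {
    return(structure(z[length(z)], status = "beyond-grid"))
  }
  # interpolate between the deepest above-level point and its neighbour
  z0 <- z[i_last]; z1 <- z[i_last + 1]
  v0 <- tv[i_last]; v1 <- tv[i_last + 1]
  ad <- if (v1 == v0) z0 else z0 + (peak - v0) / (v1 - v0) * (z1 - z0)
  structure(ad, status = "ok")
}

#' Maximum treatment time
#'
#' Irradiation time delivering the normal-tissue dose limit at the hottest
#' normal-tissue voxel: MTT = limit / max_z NT(z), in minutes.  The peak
#' search excludes the skin band (skin carries its own limit).
#'
#' @param nt_profile Weighted normal-tissue `depth_profile`, Gy/h.
#' @param dose_limit Biologically weighted limit, Gy (default 12.5).
#' @param skin_depth_cm Excluded surface band, cm.
#' @return Minutes; `Inf` for an identically zero profile.
#' @export
max_treatment_time <- function(nt_profile, dose_limit = 12.5,
                               skin_depth_cm = 0.2) {
  stopifnot(inherits(nt_profile, "depth_profile"), dose_limit > 0)
  keep <- nt_profile$depth >= skin_depth_cm
  peak <- max(nt_profile$value[keep])
  if (peak <= 0) return(Inf)
  dose_limit / peak * 60
}

#' Scale a treatment time with proton current
#'
#' Dose rate is proportional to the proton current, so a delivery time
#' scales inversely: minutes * reference / new.
#'
#' @param metric_minutes Time at the reference current, min.
#' @param reference_current_mA,new_current_mA Currents, mA (> 0).
#' @return Minutes at the new current.
#' @export
scale_with_current <- function(metric_minutes, reference_current_mA,
                               new_current_mA) {
  if (reference_current_mA <= 0 || new_current_mA <= 0)
    stop("currents must be positive")
  metric_minutes * reference_current_mA / new_current_mA
}

#' Skin dose at full delivery
#'
#' Weighted skin dose (total and four-component split) accumulated over the
#' maximum treatment time, i.e. when the brain receives its weighted dose
#' limit.
#'
#' @param skin_rates Named list/vector with components boron, nitrogen,
#'   hydrogen, gamma: weighted skin-band dose rates, Gy/h.
#' @param nt_profile Weighted normal-tissue `depth_profile` for the MTT.
#' @param dose_limit Brain limit, Gy.
#' @param skin_depth_cm Surface band excluded from the NT peak search.
#' @return list(total, components, mtt_min).
#' @export
skin_dose_at_delivery <- function(skin_rates, nt_profile, dose_limit = 12.5,
                                  skin_depth_cm = 0.2) {
  mtt <- max_treatment_time(nt_profile, dose_limit, skin_depth_cm)
  hours <- mtt / 60
  comp <- unlist(skin_rates[c("boron", "nitrogen", "hydrogen", "gamma")]) * hours
  list(total = sum(comp), components = comp, mtt_min = mtt)
}

#' Weighted skin-band dose rates
#'
#' Extracts the four-component weighted dose rates averaged over the surface
#' voxel band on the beam axis (skin role: skin CBE and skin-to-blood boron
#' ratio).
#'
#' @param components A `dose_components` at blood boron.
#' @param config A [weighting_config()].
#' @param band_cm Skin band thickness, cm (default one 2-mm voxel layer).
#' @param radius Axial averaging column radius, cm.
#' @return Named vector (boron, nitrogen, hydrogen, gamma), Gy-weighted/h.
#' @export
skin_band_rates <- function(components, config = weighting_config(),
                            band_cm = 0.2, radius = 1.0) {
  mesh <- components$mesh
  zc <- mesh_centers(mesh, 3)
  band <- which(zc <= zc[1] - 1e-9 + band_cm)
  if (!length(band)) band <- 1L
  grab <- function(map, f) mean(vapply(band, function(iz)
    axial_average(map[, , iz, drop = FALSE],
                  within_slice_mesh(mesh, iz), radius), 0)) * f
  fB <- role_cbe(config, "skin") * role_boron_factor(config, "skin")
  c(boron = grab(components$boron, fB),
    nitrogen = grab(components$nitrogen, config$rbe_nitrogen),
    hydrogen = grab(components$hydrogen, config$rbe_hydrogen),
    gamma = grab(components$gamma, config$rbe_gamma))
}

# single z-slice pseudo-mesh so axial_average can be reused
within_slice_mesh <- function(mesh, iz) {
  m <- mesh
  m$origin[3] <- mesh$origin[3] + (iz - 1) * mesh$d[3]
  m$dims[3] <- 1L
  m
}

#' Off-axis profile and flatness
#'
#' Lateral slice of a weighted dose map through the beam axis at the given
#' depth, normalized at the centre; flatness is the maximum over
#' |x| in [4, 6] cm divided by the centre value.
#'
#' @param dose_map A `weighted_dose_map` (or 3-d array with `mesh`).
#' @param depth Depth of the slice, cm.
#' @param mesh Mesh override for bare arrays.
#' @param flat_range Off-axis range (cm) scanned for the flatness ratio.
#' @return data.frame(x, value) with attributes `flatness` and `depth`.
#' @export
off_axis_profile <- function(dose_map, depth = 2.0, mesh = NULL,
                             flat_range = c(4, 6)) {
  if (is.null(mesh)) mesh <- attr(dose_map, "mesh")
  zc <- mesh_centers(mesh, 3)
  iz <- which.min(abs(zc - depth))
  yc <- mesh_centers(mesh, 2)
  iy <- which.min(abs(yc))
  xc <- mesh_centers(mesh, 1)
  vals <- dose_map[, iy, iz]
  i0 <- which.min(abs(xc))
  centre <- vals[i0]
  if (centre <= 0) stop("zero centre value at the requested depth")
  prof <- vals / centre
  sel <- abs(xc) >= flat_range[1] & abs(xc) <= flat_range[2]
  flat <- if (any(sel)) max(prof[sel]) else NA_real_
  structure(data.frame(x = xc, value = prof), flatness = flat, depth = zc[iz])
}

#' Beam figures of merit
#'
#' Convenience wrapper computing the Table-style metric row from dose
#' components: advantage depth, maximum treatment time and skin dose at
#' delivery.
#'
#' @param components A `dose_components` at blood boron.
#' @param config A [weighting_config()].
#' @param radius Axial averaging radius, cm.
#' @param skin_depth_cm Skin band, cm.
#' @return list with ad_cm, mtt_min, skin_dose_gy, profiles.
#' @export
beam_metrics <- function(components, config = weighting_config(),
                         radius = 1.0, skin_depth_cm = 0.2) {
  prof <- tumor_dose_profile(components, config, radius)
  ad <- advantage_depth(prof$tumor, prof$normal, skin_depth_cm)
  mtt <- max_treatment_time(prof$normal, config$brain_dose_limit,
                            skin_depth_cm)
  sk <- skin_dose_at_delivery(
    skin_band_rates(components, config, band_cm = skin_depth_cm,
                    radius = radius),
    prof$normal, config$brain_dose_limit, skin_depth_cm)
  list(ad_cm = as.numeric(ad), ad_status = attr(ad, "status"),
       mtt_min = mtt, skin_dose_gy = sk$total, skin_components = sk$components,
       profiles = prof)
}
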