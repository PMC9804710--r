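#' CT-number to material conversion
#'
#' Piecewise-linear Hounsfield-unit to mass-density mapping with material
#' bins (air, lung, adipose, soft tissue, bone), in the spirit of the
#' stoichiometric CT calibration used for voxel phantoms.  HU outside
#' [-1024, 3000] are clamped and counted.
#'
#' @param hu_grid Numeric array of CT numbers.
#' @return list(density = array g/cm^3, material = character array of
#'   registered material names, n_clamped = count of out-of-window values).
#' @export
ct_to_material <- function(hu_grid) {
  hu <- hu_grid
  n_clamped <- sum(hu < -1024 | hu > 3000)
  hu[hu < -1024] <- -1024
  hu[hu > 3000] <- 3000
  # density breakpoints (HU, g/cm^3): monotone non-decreasing
  bp_hu <- c(-1024, -1000, -98, 0, 14, 23, 100, 1600, 3000)
  bp_rho <- c(0.00121, 0.00121, 0.93, 1.00, 1.03, 1.031, 1.119, 1.964, 2.80)
  rho <- approx(bp_hu, bp_rho, xout = as.numeric(hu), rule = 2)$y
  mat <- rep("soft_tissue", length(hu))
  mat[hu < -950] <- "air"
  mat[hu >= -950 & hu < -120] <- "lung"
  mat[hu >= -120 & hu < -20] <- "adipose"
  mat[hu >= 120] <- "bone_cortical"
  out_rho <- array(rho, dim = if (is.null(dim(hu))) length(hu) else dim(hu))
  out_mat <- array(mat, dim = dim(out_rho))
  list(density = out_rho, material = out_mat, n_clamped = n_clamped)
}

new_voxel_phantom <- function(labels, label_materials, density, voxsize,
                              origin, masks) {
  structure(list(labels = labels, label_materials = label_materials,
                 density = density, voxsize = voxsize, origin = origin,
                 dims = dim(labels), masks = masks),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %s voxels of %s cm; masks: %s\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxsize, 3), collapse = "x"),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Synthetic voxel head phantom
#'
#' A layered head on a 2-mm grid standing in for a CT-derived patient
#' volume: scalp (skin) shell, skull (cortical bone) shell and brain
#' ellipsoid, with four 2-cm diameter spherical mock tumors - at 4, 6 and
#' 8 cm depth along the beam axis and at 8 cm depth displaced 4 cm off-axis.
#' The vertex touches z = 0 and the beam enters from the vertex along +z.
#' Boolean masks are provided for each tumor, the brain and the body region;
#' tumor masks lie inside the brain mask and are mutually disjoint.
#'
#' @param voxel_cm Voxel edge, cm (default 0.2, a 2-mm cube).
#' @param half_width_cm,half_length_cm Outer head semi-axes (x/y and z).
#' @param scalp_cm,skull_cm Shell thicknesses.
#' @return A `voxel_phantom`.
#' @export
make_head_phantom <- function(voxel_cm = 0.2, half_width_cm = 7.8,
                              half_length_cm = 9.6, scalp_cm = 0.5,
                              skull_cm = 0.7) {
  a <- half_width_cm
  c_ <- half_length_cm
  nx <- ny <- 2L * as.integer(ceiling((a + 0.4) / voxel_cm)) + 1L
  nz <- as.integer(ceiling(2 * c_ / voxel_cm)) + 1L
  # half-voxel shift puts voxel centres on the landmark lattice (beam axis,
  # integer tumor depths), which keeps sphere voxelization errors ~1%
  origin <- c(-(nx / 2) * voxel_cm, -(ny / 2) * voxel_cm, -voxel_cm / 2)
  xc <- origin[1] + (seq_len(nx) - 0.5) * voxel_cm
  yc <- origin[2] + (seq_len(ny) - 0.5) * voxel_cm
  zc <- origin[3] + (seq_len(nz) - 0.5) * voxel_cm
  X <- array(rep(xc, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(yc, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), dim = c(nx, ny, nz))
  # nested ellipsoids, outer vertex at z = 0, shells shrunk by thickness
  head_m <- (X / a)^2 + (Y / a)^2 + ((Z - c_) / c_)^2 <= 1
  skull_m <- (X / (a - scalp_cm))^2 + (Y / (a - scalp_cm))^2 +
    ((Z - c_) / (c_ - scalp_cm))^2 <= 1
  brain_m <- (X / (a - scalp_cm - skull_cm))^2 +
    (Y / (a - scalp_cm - skull_cm))^2 +
    ((Z - c_) / (c_ - scalp_cm - skull_cm))^2 <= 1
  label_materials <- c("air", "skin_icrp", "bone_cortical", "brain_icrp")
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[head_m] <- 1L
  labels[skull_m] <- 2L
  labels[brain_m] <- 3L
  tumor_centres <- list(t1 = c(0, 0, 4), t2 = c(0, 0, 6),
                        t3 = c(0, 0, 8), t4 = c(4, 0, 8))
  masks <- list()
  for (nm in names(tumor_centres)) {
    ce <- tumor_centres[[nm]]
    m <- (X - ce[1])^2 + (Y - ce[2])^2 + (Z - ce[3])^2 <= 1.0
    masks[[sub("^t", "tumor", nm)]] <- m & brain_m
  }
  masks$brain <- brain_m
  masks$body <- labels > 0L
  rho <- vapply(label_materials, function(nm) get_material(nm)$density, 0)
  density <- array(rho[labels + 1L], dim = dim(labels))
  new_voxel_phantom(labels, label_materials, density,
                    rep(voxel_cm, 3), origin, masks)
}

#' Import a labelled voxel volume
#'
#' Builds a `voxel_phantom` from a user-supplied HU volume (converted via
#' [ct_to_material()]) or a direct label volume with a label -> material map.
#'
#' @param hu_grid Optional 3-d array of CT numbers.
#' @param labels Optional 3-d integer array (0-based labels).
#' @param label_materials Character vector mapping label value k to
#'   `label_materials[k + 1]`.
#' @param voxel_cm Voxel size (scalar or length 3).
#' @param origin Grid origin, cm.
#' @param masks Named list of logical arrays.
#' @return A `voxel_phantom`.
#' @export
voxel_phantom <- function(hu_grid = NULL, labels = NULL,
                          label_materials = NULL, voxel_cm = 0.2,
                          origin = NULL, masks = list()) {
  voxel_cm <- rep(voxel_cm, length.out = 3)
  if (!is.null(hu_grid)) {
    conv <- ct_to_material(hu_grid)
    label_materials <- sort(unique(as.vector(conv$material)))
    labels <- array(match(conv$material, label_materials) - 1L,
                    dim = dim(conv$density))
    density <- conv$density
  } else {
    stopifnot(!is.null(labels), !is.null(label_materials))
    rho <- vapply(label_materials, function(nm) get_material(nm)$density, 0)
    density <- array(rho[labels + 1L], dim = dim(labels))
  }
  if (is.null(origin))
    origin <- c(-dim(labels)[1] / 2 * voxel_cm[1],
                -dim(labels)[2] / 2 * voxel_cm[2], 0)
  new_voxel_phantom(labels, label_materials, density, voxel_cm, origin, masks)
}
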