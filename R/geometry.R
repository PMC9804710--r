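#' Filter design specification
#'
#' Three LiF filter configurations at the collimator exit: design A is a
#' uniform disc covering the full 12-cm bore; design B is a centred square
#' plate partially covering the beam exit; design C stacks the uniform disc
#' and the centred square.
#'
#' @param design "A", "B" or "C".
#' @param disc_thickness_mm Disc thickness (designs A and C).
#' @param disc_diameter_cm Disc diameter (default 12, the bore).
#' @param square_side_cm Square plate side, 4 or 8 cm (designs B and C).
#' @param square_thickness_mm Square plate thickness (designs B and C).
#' @return A `filter_design` object (or NULL semantics via `NULL` filter in
#'   [build_scene()] for the unfiltered beam).
#' @export
filter_design <- function(design = c("A", "B", "C"),
                          disc_thickness_mm = 5,
                          disc_diameter_cm = 12,
                          square_side_cm = 8,
                          square_thickness_mm = 5) {
  design <- match.arg(design)
  has_disc <- design %in% c("A", "C")
  has_square <- design %in% c("B", "C")
  if (has_disc && disc_thickness_mm <= 0) stop("disc thickness must be > 0")
  if (has_square && square_thickness_mm <= 0) stop("square thickness must be > 0")
  structure(
    list(design = design,
         disc_diameter_cm = if (has_disc) disc_diameter_cm else NA_real_,
         disc_thickness_mm = if (has_disc) disc_thickness_mm else NA_real_,
         square_side_cm = if (has_square) square_side_cm else NA_real_,
         square_thickness_mm = if (has_square) square_thickness_mm else NA_real_),
    class = "filter_design"
  )
}

new_scene <- function(regions, materials, bbox, phantom = NULL, meta = list()) {
  for (nm in materials) {
    if (is.null(material_registry()[[nm]]))
      stop("unregistered material in scene: ", nm)
  }
  structure(list(regions = regions, materials = materials, bbox = bbox,
                 phantom = phantom, meta = meta),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d regions, materials: %s\n", nrow(x$regions),
              paste(unique(x$regions$material), collapse = ", ")))
  if (!is.null(x$phantom))
    cat(sprintf("  voxel phantom: %s voxels\n",
                paste(x$phantom$dims, collapse = "x")))
  invisible(x)
}

region_row <- function(type, p, material, priority) {
  data.frame(type = type, p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
             p5 = p[5], p6 = p[6], material = material, priority = priority,
             stringsAsFactors = FALSE)
}

# filter regions stacked upstream from the bore exit plane z = z_exit
filter_regions <- function(filter, z_exit, bore_radius, material, priority) {
  if (is.null(filter)) return(NULL)
  rows <- NULL
  z <- z_exit
  if (!is.na(filter$disc_thickness_mm)) {
    t_cm <- filter$disc_thickness_mm / 10
    r <- filter$disc_diameter_cm / 2
    rows <- rbind(rows, region_row("cylinder", c(0, 0, r, z - t_cm, z, 0),
                                   material, priority))
    z <- z - t_cm
  }
  if (!is.na(filter$square_side_cm)) {
    if (filter$square_side_cm > 2 * bore_radius)
      stop("square plate larger than the collimator bore")
    h <- filter$square_side_cm / 2
    t_cm <- filter$square_thickness_mm / 10
    rows <- rbind(rows, region_row("box", c(-h, h, -h, h, z - t_cm, z),
                                   material, priority))
  }
  rows
}

#' Build a collimated beam + phantom scene
#'
#' Assembles the transport scene: an absorbing LiF-polyethylene collimator
#' annulus with a 12-cm bore, the requested filter design flush against the
#' bore exit, optional air gap, and a cubic phantom whose entry face sits at
#' z = 0 (the beam travels +z; the source plane lives at negative z).
#'
#' @param filter A [filter_design()] or NULL for the unfiltered beam.
#' @param phantom_material Registered material name for the phantom cube.
#' @param phantom_size_cm Phantom cube side (default 20).
#' @param collimator_diameter_cm Bore diameter (default 12).
#' @param collimator_length_cm Collimator length upstream of the exit
#'   (default 10; not stated by the design study, config-overridable).
#' @param collimator_outer_cm Collimator outer half-width.
#' @param filter_material Registered material name of the filter (default
#'   the 99% 6Li-enriched LiF of the simulated design; "lif_asbuilt" gives
#'   the manufactured 60/40 sinter).
#' @param air_gap_cm Gap between filter/bore exit and the phantom face.
#' @param background_material Medium filling unclaimed space (default "air";
#'   "void" gives idealized validation scenes with no parasitic scatter).
#' @return A `scene`.
#' @export
build_scene <- function(filter = NULL,
                        phantom_material = "water",
                        phantom_size_cm = 20,
                        collimator_diameter_cm = 12,
                        collimator_length_cm = 10,
                        collimator_outer_cm = 20,
                        filter_material = "lif_enriched",
                        air_gap_cm = 0,
                        background_material = "air") {
  bore <- collimator_diameter_cm / 2
  half <- phantom_size_cm / 2
  z_exit <- -air_gap_cm
  zmin <- min(-collimator_length_cm - air_gap_cm, -9) - 1
  ext <- max(collimator_outer_cm, half) + 1
  bbox <- c(-ext, ext, -ext, ext, zmin, phantom_size_cm + 1)
  regions <- region_row("box", bbox, background_material, 0)
  regions <- rbind(regions, region_row(
    "annulus", c(bore, collimator_outer_cm,
                 z_exit - collimator_length_cm, z_exit, 0, 0),
    "lif_polyethylene", 1))
  fr <- filter_regions(filter, z_exit, bore, filter_material, 2)
  if (!is.null(fr)) regions <- rbind(regions, fr)
  regions <- rbind(regions, region_row(
    "box", c(-half, half, -half, half, 0, phantom_size_cm),
    phantom_material, 3))
  mats <- unique(regions$material)
  new_scene(regions, mats, bbox,
            meta = list(filter = filter, phantom_material = phantom_material,
                        phantom_size_cm = phantom_size_cm,
                        bore_radius = bore, z_exit = z_exit))
}

#' Build a scene around a voxel phantom
#'
#' Replaces the cubic phantom with a voxelized patient/head volume whose
#' vertex touches the beam exit plane at z = 0 (beam entering from the
#' vertex along +z).
#'
#' @param phantom A `voxel_phantom` (see [make_head_phantom()]).
#' @inheritParams build_scene
#' @return A `scene` with an attached voxel block.
#' @export
build_patient_scene <- function(phantom,
                                filter = NULL,
                                collimator_diameter_cm = 12,
                                collimator_length_cm = 10,
                                collimator_outer_cm = 20,
                                filter_material = "lif_enriched",
                                air_gap_cm = 0) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  bore <- collimator_diameter_cm / 2
  z_exit <- -air_gap_cm
  ex <- phantom$origin + phantom$dims * phantom$voxsize
  ext <- max(collimator_outer_cm, abs(phantom$origin[1:2]), abs(ex[1:2])) + 1
  zmin <- -collimator_length_cm - air_gap_cm - 9
  bbox <- c(-ext, ext, -ext, ext, zmin, ex[3] + 1)
  regions <- region_row("box", bbox, "air", 0)
  regions <- rbind(regions, region_row(
    "annulus", c(bore, collimator_outer_cm,
                 z_exit - collimator_length_cm, z_exit, 0, 0),
    "lif_polyethylene", 1))
  fr <- filter_regions(filter, z_exit, bore, filter_material, 2)
  if (!is.null(fr)) regions <- rbind(regions, fr)
  mats <- unique(c(regions$material, phantom$label_materials))
  matidx <- match(phantom$label_materials, mats)[phantom$labels + 1L]
  ph <- list(box = c(phantom$origin[1], ex[1], phantom$origin[2], ex[2],
                     phantom$origin[3], ex[3]),
             origin = phantom$origin, voxsize = phantom$voxsize,
             dims = as.integer(phantom$dims),
             matidx = as.integer(matidx),
             dens = as.numeric(phantom$density))
  new_scene(regions, mats, bbox, phantom = ph,
            meta = list(filter = filter, phantom_material = "voxel",
                        bore_radius = bore, z_exit = z_exit,
                        voxel_phantom = phantom))
}

# internal: scene -> list consumed by the C++ kernel
as_cpp_scene <- function(scene) {
  tcode <- c(box = 0, cylinder = 1, annulus = 2)
  r <- scene$regions
  m <- cbind(tcode[r$type], r$p1, r$p2, r$p3, r$p4, r$p5, r$p6,
             match(r$material, scene$materials), r$priority)
  list(regions = unname(m), bbox = scene$bbox, phantom = scene$phantom)
}

scene_cpp_materials <- function(scene) {
  lapply(scene$materials, function(nm) as_cpp_material(get_material(nm)))
}

#' Locate points in a scene
#'
#' Resolves each point to the highest-priority region containing it (voxel
#' phantom winning where present).  Points outside the scene bounding box
#' map to the escape sentinel `"<escape>"`.
#'
#' @param scene A `scene`.
#' @param points Numeric vector (x, y, z) or 3-column matrix.
#' @return Character vector of material names.
#' @export
locate <- function(scene, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  idx <- cpp_locate(as_cpp_scene(scene), points)
  out <- rep("<escape>", length(idx))
  out[idx > 0] <- scene$materials[idx[idx > 0]]
  out
}

#' Distance to the nearest region boundary
#'
#' Exact ray-surface distance along `direction` to the nearest surface where
#' some region's containment changes (or the bounding box is exited).
#' Rays sitting exactly on a face are pushed off by an epsilon, so the
#' result is always strictly positive.
#'
#' @param scene A `scene`.
#' @param position Numeric (x, y, z), inside the bounding box.
#' @param direction Unit 3-vector.
#' @return Distance in cm.
#' @export
distance_to_boundary <- function(scene, position, direction) {
  direction <- direction / sqrt(sum(direction^2))
  cpp_distance(as_cpp_scene(scene), as.numeric(position),
               as.numeric(direction))
}
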