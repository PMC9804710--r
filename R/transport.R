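#' Transport run specification
#'
#' @param n_particles Number of source histories (> 0).
#' @param seed Integer seed; the same seed and configuration give bit-identical
#'   tallies.
#' @param n_batches History batches for statistical errors (>= 2, default 20).
#' @param photon_transport Transport photons (source gammas and 2.223 MeV
#'   hydrogen-capture gammas)?
#' @param implicit_capture Survival-biased capture with Russian roulette
#'   (threshold weight 0.01, survival weight 0.1) instead of analog capture.
#' @param target_relerr Optional stopping rule: stop after the batch where the
#'   relative standard error at the monitor voxel drops below this (the
#'   particle budget is the cap).
#' @param monitor_point Depth-monitor location, cm (default on axis at 15 cm
#'   depth).
#' @param free_gas_cut_eV Free-gas thermal target motion below this energy.
#' @param recoil_cut_eV Hydrogen-recoil kerma scored above this energy.
#' @return A `run_spec` object.
#' @export
run_spec <- function(n_particles, seed = 1L, n_batches = 20L,
                     photon_transport = TRUE, implicit_capture = FALSE,
                     target_relerr = NULL, monitor_point = c(0, 0, 15),
                     free_gas_cut_eV = 1.0, recoil_cut_eV = THERMAL_CUT_EV) {
  stopifnot(n_particles > 0, n_batches >= 2)
  structure(list(n_particles = n_particles, seed = as.integer(seed),
                 n_batches = as.integer(n_batches),
                 photon_transport = isTRUE(photon_transport),
                 implicit_capture = isTRUE(implicit_capture),
                 target_relerr = target_relerr,
                 monitor_point = monitor_point,
                 free_gas_cut_eV = free_gas_cut_eV,
                 recoil_cut_eV = recoil_cut_eV),
            class = "run_spec")
}

#' Tally mesh over the phantom
#'
#' @param scene A `scene`.
#' @param bin Bin size per axis, cm (recycled to length 3).  0.2 cm is the
#'   design-sweep default; profile runs may use finer z bins.
#' @return Mesh description (origin, dims, d).
#' @export
tally_mesh <- function(scene, bin = 0.2) {
  bin <- rep(bin, length.out = 3)
  if (!is.null(scene$phantom)) {
    org <- scene$phantom$origin
    ext <- scene$phantom$dims * scene$phantom$voxsize
  } else {
    sz <- scene$meta$phantom_size_cm
    org <- c(-sz / 2, -sz / 2, 0)
    ext <- c(sz, sz, sz)
  }
  dims <- pmax(1L, as.integer(round(ext / bin)))
  list(origin = org, dims = dims, d = ext / dims)
}

mesh_centers <- function(mesh, axis) {
  mesh$origin[axis] + (seq_len(mesh$dims[axis]) - 0.5) * mesh$d[axis]
}

#' Run Monte Carlo transport
#'
#' Analog (or implicit-capture) neutron/photon transport of the source
#' through the scene, scoring track-length fluence per voxel in the three
#' conventional energy bands, 1/v-folded capture-rate tallies, hydrogen
#' recoil kerma, photon fluence and energy deposition, and analog per-voxel
#' capture counts per reaction channel.  Fluence values are cm^-2 per source
#' particle (scored track length / voxel volume / histories, the track-length
#' estimator); errors come from history batching.
#'
#' @param source A `source_model`.
#' @param scene A `scene`.
#' @param runspec A [run_spec()].
#' @param tally Optional mesh from [tally_mesh()]; default 2-mm bins over the
#'   phantom.
#' @return A `tally_bundle`.
#' @export
run_transport <- function(source, scene, runspec, tally = NULL) {
  stopifnot(inherits(source, "source_model"), inherits(scene, "scene"),
            inherits(runspec, "run_spec"))
  if (is.null(tally)) tally <- tally_mesh(scene)
  k <- nuclear_constants()
  mon <- runspec$monitor_point
  mi <- floor((mon - tally$origin) / tally$d)
  monitor <- if (all(mi >= 0 & mi < tally$dims))
    mi[1] + tally$dims[1] * (mi[2] + tally$dims[2] * mi[3]) else -1
  run <- list(n = as.numeric(runspec$n_particles),
              nbatch = runspec$n_batches,
              photons = runspec$photon_transport,
              implicit = runspec$implicit_capture,
              fg_cut = runspec$free_gas_cut_eV,
              kT = k$meta$kT_eV,
              recoil_cut = runspec$recoil_cut_eV,
              s0_b10 = k$nuclides$B10$sigma0_capture,
              s0_n14 = k$nuclides$N14$sigma0_capture,
              monitor = as.numeric(monitor),
              target_relerr = if (is.null(runspec$target_relerr)) 0
                              else runspec$target_relerr,
              seed = as.numeric(runspec$seed))
  raw <- cpp_transport(as_cpp_source(source), as_cpp_scene(scene),
                       scene_cpp_materials(scene), tally, run)
  dims <- tally$dims
  arr <- function(x) array(x, dim = dims)
  nflux <- array(unlist(raw$nflux), dim = c(dims, 3))
  relerr <- array(unlist(raw$nflux_relerr), dim = c(dims, 3))
  # per-voxel material / density maps
  if (!is.null(scene$phantom) &&
      isTRUE(all.equal(scene$phantom$dims, dims)) &&
      isTRUE(all.equal(scene$phantom$voxsize, tally$d, tolerance = 1e-9))) {
    matidx <- array(scene$phantom$matidx, dim = dims)
    dens <- array(scene$phantom$dens, dim = dims)
  } else {
    ctr <- as.matrix(expand.grid(x = mesh_centers(tally, 1),
                                 y = mesh_centers(tally, 2),
                                 z = mesh_centers(tally, 3)))
    idx <- cpp_locate(as_cpp_scene(scene), ctr)
    idx[idx <= 0] <- match(scene$regions$material[1], scene$materials)
    matidx <- arr(idx)
    rho <- vapply(scene$materials, function(nm) get_material(nm)$density, 0)
    dens <- arr(rho[idx])
  }
  structure(
    list(mesh = tally,
         neutron = list(value = nflux, rel_err = relerr,
                        group_edges = c(0, THERMAL_CUT_EV, EPI_CUT_EV, Inf)),
         photon = list(flux = arr(raw$pflux), edep = arr(raw$pedep)),
         onev_sub = arr(raw$onev_sub), onev_epi = arr(raw$onev_epi),
         b10_fold = arr(raw$b10_fold), n14_fold = arr(raw$n14_fold),
         h_kerma = arr(raw$h_kerma),
         capture_counts = list(b10 = arr(raw$capture_counts[[1]]),
                               li6 = arr(raw$capture_counts[[2]]),
                               n14 = arr(raw$capture_counts[[3]]),
                               h_ng = arr(raw$capture_counts[[4]])),
         matidx = matidx, dens = dens, materials = scene$materials,
         counters = raw[c("histories", "absorbed", "escaped", "lost",
                          "n_primaries", "g_primaries", "g_absorbed",
                          "g_escaped", "secondary_photons")],
         batches = raw[c("tl_cap_batches", "an_cap_batches",
                         "monitor_batches", "nbatches", "monitor_relerr")],
         source_strength = source$strength,
         seed = runspec$seed),
    class = "tally_bundle")
}

#' @export
print.tally_bundle <- function(x, ...) {
  cat(sprintf(paste0("<tally_bundle> %s mesh, %g histories ",
                     "(absorbed %.3g, escaped %.3g), monitor relerr %.3g\n"),
              paste(x$mesh$dims, collapse = "x"), x$counters$histories,
              x$counters$absorbed, x$counters$escaped,
              x$batches$monitor_relerr))
  invisible(x)
}

band_index <- function(band = c("thermal", "epithermal", "fast", "total")) {
  band <- match.arg(band)
  switch(band, thermal = 1L, epithermal = 2L, fast = 3L, total = 0L)
}

band_map <- function(bundle, band) {
  b <- band_index(band)
  if (b == 0L) {
    bundle$neutron$value[, , , 1] + bundle$neutron$value[, , , 2] +
      bundle$neutron$value[, , , 3]
  } else bundle$neutron$value[, , , b]
}

# average a voxel map over the axial column of given radius, per depth slice
axial_average <- function(map, mesh, radius) {
  xc <- mesh_centers(mesh, 1)
  yc <- mesh_centers(mesh, 2)
  r2 <- outer(xc^2, yc^2, "+")
  keep <- r2 <= radius^2
  if (!any(keep)) keep[which.min(r2)] <- TRUE
  nz <- mesh$dims[3]
  out <- numeric(nz)
  for (iz in seq_len(nz)) {
    sl <- map[, , iz]
    out[iz] <- mean(sl[keep])
  }
  out
}

#' Axial depth profile of a tally or dose map
#'
#' Averages a per-voxel map over the on-axis column of the given radius and
#' returns value versus depth.
#'
#' @param bundle A `tally_bundle` (or a bare 3-d array with `mesh` supplied).
#' @param what One of "thermal", "epithermal", "fast", "total" (neutron
#'   fluence bands), "photon_flux", "photon_edep".
#' @param radius Averaging column radius, cm.
#' @param mesh Mesh override when `bundle` is a bare array.
#' @return A `depth_profile` data.frame (depth, value).
#' @export
axial_profile <- function(bundle, what = "thermal", radius = 1.0, mesh = NULL) {
  if (is.array(bundle) && !is.null(mesh)) {
    map <- bundle
  } else {
    mesh <- bundle$mesh
    map <- switch(what,
                  photon_flux = bundle$photon$flux,
                  photon_edep = bundle$photon$edep,
                  band_map(bundle, what))
  }
  depth_profile(mesh_centers(mesh, 3), axial_average(map, mesh, radius))
}

#' @rdname axial_profile
#' @param depth,value Depth grid (cm, strictly ascending) and values.
#' @export
depth_profile <- function(depth, value) {
  stopifnot(length(depth) == length(value), all(diff(depth) > 0))
  structure(data.frame(depth = depth, value = value),
            class = c("depth_profile", "data.frame"))
}

#' Per-voxel capture-rate map
#'
#' Reactions per cm^3 per source particle for one capture channel, by either
#' estimator: "track" folds the 1/v track-length tally with the channel's
#' local number density and 2200 m/s cross section; "collision" uses the
#' analog capture counts.  The two agree within statistics on any analog run.
#'
#' @param bundle A `tally_bundle`.
#' @param channel "b10", "li6", "n14" or "h_ng".
#' @param estimator "track" or "collision".
#' @return 3-d array of rates.
#' @export
capture_rate_map <- function(bundle, channel = c("b10", "li6", "n14", "h_ng"),
                             estimator = c("track", "collision")) {
  channel <- match.arg(channel)
  estimator <- match.arg(estimator)
  if (estimator == "collision") return(bundle$capture_counts[[channel]])
  nuc <- switch(channel, b10 = "B10", li6 = "Li6", n14 = "N14", h_ng = "H1")
  k <- nuclear_constants()
  s0 <- k$nuclides[[nuc]]$sigma0_capture
  # per-material channel number density, scaled by local density
  Nmat <- vapply(bundle$materials, function(nm) {
    v <- get_material(nm)$number_densities[nuc]
    if (is.na(v)) 0 else unname(v)
  }, 0)
  rho <- vapply(bundle$materials, function(nm) get_material(nm)$density, 0)
  Nvox <- Nmat[bundle$matidx] * bundle$dens / rho[bundle$matidx]
  array(Nvox, dim = dim(bundle$onev_sub)) * s0 *
    (bundle$onev_sub + bundle$onev_epi)
}
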