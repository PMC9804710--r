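#' Box-smooth a voxel map
#'
#' Separable running-mean filter of half-width `w` voxels per axis with edge
#' replication.  Used to stabilise voxel-level extrema (normalization maxima,
#' DVH percentiles) of desk-scale Monte Carlo dose maps; a half-width of one
#' 2-mm voxel (6-mm kernel) preserves the cm-scale depth gradients of a
#' therapeutic beam.
#'
#' @param arr 3-d numeric array.
#' @param w Half-width in voxels (0 returns the input).
#' @return Smoothed array of the same shape.
#' @export
box_smooth <- function(arr, w = 1L) {
  if (w <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    idx <- lapply(seq_len(2 * w + 1) - w - 1L,
                  function(s) pmin(pmax(seq_len(n) + s, 1L), n))
    acc <- array(0, d)
    for (ix in idx) {
      acc <- acc + switch(ax,
                          arr[ix, , , drop = FALSE],
                          arr[, ix, , drop = FALSE],
                          arr[, , ix, drop = FALSE])
    }
    arr <- acc / (2 * w + 1)
  }
  arr
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level.
#' The curve starts at 1.0 (every voxel receives >= 0) and is monotone
#' non-increasing down to 0 beyond the maximum dose.
#'
#' @param dose_map Numeric array of (weighted) voxel doses, Gy.
#' @param mask Logical array of the structure (non-empty, same shape).
#' @param n_bins Number of dose bins (default 200).
#' @return A `dvh_curve` data.frame (dose, vol_frac).
#' @export
compute_dvh <- function(dose_map, mask, n_bins = 200) {
  if (!any(mask)) stop("empty structure mask")
  if (!all(dim(dose_map) == dim(mask))) stop("dose/mask shape mismatch")
  d <- as.numeric(dose_map[mask])
  top <- max(d)
  edges <- seq(0, if (top > 0) top * (1 + 1e-9) else 1, length.out = n_bins + 1)
  vol <- vapply(edges, function(e) mean(d >= e), 0)
  vol[1] <- 1.0
  structure(data.frame(dose = edges, vol_frac = vol),
            class = c("dvh_curve", "data.frame"))
}

#' Dose percentile D_p
#'
#' D_p is the minimum dose received by the hottest p% of the structure: the
#' largest dose d such that at least p% of the volume receives >= d.
#' Computed on the voxel doses without interpolation.
#'
#' @param x Numeric vector/array of masked voxel doses, or a `dvh_curve`.
#' @param p Percentile in (0, 100).
#' @return Dose in Gy.
#' @export
dose_percentile <- function(x, p) {
  if (any(p <= 0 | p >= 100)) stop("p must be in (0, 100)")
  if (inherits(x, "dvh_curve")) {
    vapply(p, function(pp) {
      ok <- x$vol_frac >= pp / 100
      max(x$dose[ok])
    }, 0)
  } else {
    d <- sort(as.numeric(x), decreasing = TRUE)
    n <- length(d)
    vapply(p, function(pp) d[ceiling(pp / 100 * n)], 0)
  }
}

#' Homogeneity index
#'
#' HI = D5 / D95: the ratio of the near-maximum to the near-minimum dose of
#' a structure; 1.0 is perfectly homogeneous.
#'
#' @param d5,d95 Dose percentiles, Gy (d95 > 0).
#' @return Dimensionless index.
#' @export
homogeneity_index <- function(d5, d95) {
  if (any(d95 <= 0)) stop("D95 must be positive")
  d5 / d95
}

#' DVH metric table for a set of structures
#'
#' D5, D98, D50, D95 and the homogeneity index per structure, in the layout
#' of a DVH parameter table.
#'
#' @param dose_map Weighted dose array, Gy.
#' @param masks Named list of logical structure masks.
#' @return data.frame(structure, D5, D98, D50, D95, HI).
#' @export
dvh_table <- function(dose_map, masks) {
  rows <- lapply(names(masks), function(nm) {
    d <- as.numeric(dose_map[masks[[nm]]])
    ps <- dose_percentile(d, c(5, 98, 50, 95))
    data.frame(structure = nm, D5 = ps[1], D98 = ps[2], D50 = ps[3],
               D95 = ps[4],
               HI = if (ps[4] > 0) homogeneity_index(ps[1], ps[4]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export DVH curves as CSV
#'
#' Long-format CSV (structure, dose_gy, vol_frac), full precision.
#'
#' @param dose_map Weighted dose array, Gy.
#' @param masks Named list of structure masks.
#' @param path Output file.
#' @param n_bins Bins per curve.
#' @export
write_dvh_csv <- function(dose_map, masks, path, n_bins = 200) {
  rows <- lapply(names(masks), function(nm) {
    cv <- compute_dvh(dose_map, masks[[nm]], n_bins)
    data.frame(structure = nm, dose_gy = cv$dose, vol_frac = cv$vol_frac)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
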