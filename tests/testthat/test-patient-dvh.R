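test_that("HU conversion hits the scale anchors and is monotone", {
  conv <- ct_to_material(array(c(-1000, 0, 500, -2000, 3500), dim = c(5, 1, 1)))
  expect_lt(conv$density[1], 0.01)              # air end of the HU scale
  expect_equal(conv$density[2], 1.0)            # HU 0 = water density
  expect_equal(conv$n_clamped, 2)
  expect_equal(conv$material[1], "air")
  expect_equal(conv$material[3], "bone_cortical")
  hu <- seq(-1024, 3000, by = 8)
  rho <- ct_to_material(array(hu, dim = c(length(hu), 1, 1)))$density
  expect_true(all(diff(rho) >= 0))
})

test_that("head phantom geometry: tumor placement, volumes, masks", {
  ph <- make_head_phantom()
  vox <- prod(ph$voxsize)
  sphere <- 4 / 3 * pi * 1^3
  centroid_depth <- function(m) {
    zc <- ph$origin[3] + (seq_len(ph$dims[3]) - 0.5) * ph$voxsize[3]
    idx <- which(m, arr.ind = TRUE)
    mean(zc[idx[, 3]])
  }
  for (i in 1:4) {
    m <- ph$masks[[paste0("tumor", i)]]
    expect_lt(abs(sum(m) * vox - sphere) / sphere, 0.05)
    expect_equal(centroid_depth(m), c(4, 6, 8, 8)[i],
                 tolerance = ph$voxsize[3] / 2)
    expect_true(all(ph$masks$brain[m]))
  }
  # off-axis displacement of tumor 4
  xc <- ph$origin[1] + (seq_len(ph$dims[1]) - 0.5) * ph$voxsize[1]
  i4 <- which(ph$masks$tumor4, arr.ind = TRUE)
  expect_equal(mean(xc[i4[, 1]]), 4, tolerance = 0.1)
  # pairwise disjoint
  tot <- ph$masks$tumor1 + ph$masks$tumor2 + ph$masks$tumor3 + ph$masks$tumor4
  expect_true(all(tot <= 1))
  # vertex touches z = 0: body present in the first slice
  expect_true(any(ph$masks$body[, , 1]))
  expect_true(all(ph$density[ph$masks$body] > 0))
})

test_that("DVH curve: uniform dose step and curve invariants", {
  mask <- array(TRUE, dim = c(5, 5, 5))
  cv <- compute_dvh(array(7, dim = c(5, 5, 5)), mask, n_bins = 100)
  expect_equal(cv$vol_frac[1], 1.0)
  expect_true(all(diff(cv$vol_frac) <= 0))
  expect_equal(cv$vol_frac[length(cv$vol_frac)], 0)
  expect_true(all(cv$vol_frac[cv$dose < 7] == 1))
  # differential DVH integrates to one
  expect_equal(sum(-diff(cv$vol_frac)), 1)
  expect_error(compute_dvh(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
})

test_that("percentile convention forced by the two-level example", {
  x <- c(rep(10, 50), rep(20, 50))
  expect_equal(dose_percentile(x, 95), 10)
  expect_equal(dose_percentile(x, 5), 20)
  expect_equal(dose_percentile(rep(4.2, 99), c(2, 50, 98)), rep(4.2, 3))
})

test_that("percentiles agree with a sorting oracle on random grids", {
  set.seed(5)
  for (trial in 1:20) {
    x <- rgamma(1e3, shape = 2, scale = runif(1, 0.5, 5))
    for (p in c(2, 5, 50, 95, 98)) {
      s <- sort(x, decreasing = TRUE)
      expect_equal(dose_percentile(x, p), s[ceiling(p / 100 * length(x))])
    }
    ps <- dose_percentile(x, c(98, 95, 50, 5))
    expect_true(all(diff(ps) >= 0))  # D98 <= D95 <= D50 <= D5
    # curve-based percentiles agree with voxel-based at bin resolution
    mask <- array(TRUE, dim = c(10, 10, 10))
    cv <- compute_dvh(array(x, dim = c(10, 10, 10)), mask, n_bins = 4000)
    expect_equal(dose_percentile(cv, 50), dose_percentile(x, 50),
                 tolerance = max(x) / 2000)
  }
})

test_that("homogeneity index arithmetic", {
  expect_equal(homogeneity_index(5, 5), 1.0)
  expect_equal(round(homogeneity_index(69.7, 55.4), 1), 1.3)
  expect_equal(round(homogeneity_index(24.0, 14.4), 1), 1.7)
  expect_error(homogeneity_index(1, 0), "positive")
})

test_that("dvh_table and CSV export produce the clinical DVH-table layout", {
  set.seed(8)
  dose <- array(rgamma(1000, 3), dim = c(10, 10, 10))
  masks <- list(a = array(c(TRUE, FALSE), dim = c(10, 10, 10)),
                b = array(TRUE, dim = c(10, 10, 10)))
  tb <- dvh_table(dose, masks)
  expect_equal(names(tb), c("structure", "D5", "D98", "D50", "D95", "HI"))
  expect_equal(tb$HI, tb$D5 / tb$D95)
  f <- tempfile(fileext = ".csv")
  write_dvh_csv(dose, masks, f)
  back <- read.csv(f)
  expect_equal(unique(back$structure), c("a", "b"))
  expect_equal(min(back$vol_frac), 0)
})

test_that("voxel_phantom imports labels or HU volumes", {
  lab <- array(0L, dim = c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
  ph <- voxel_phantom(labels = lab, label_materials = c("air", "water"),
                      voxel_cm = 0.5)
  expect_equal(ph$density[2, 2, 2], 1.0)
  expect_equal(ph$density[1, 1, 1], get_material("air")$density)
  hu <- array(-1000, dim = c(4, 4, 4)); hu[2:3, 2:3, 2:3] <- 0
  ph2 <- voxel_phantom(hu_grid = hu, voxel_cm = 0.5)
  expect_equal(ph2$density[2, 2, 2], 1.0)
})

test_that("box smoothing preserves means and flattens noise", {
  set.seed(2)
  a <- array(rnorm(8000, mean = 5), dim = c(20, 20, 20))
  s <- box_smooth(a, 1)
  expect_equal(mean(s), mean(a), tolerance = 0.01)
  expect_lt(sd(s), sd(a) / 2)
  expect_identical(box_smooth(a, 0), a)
})
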