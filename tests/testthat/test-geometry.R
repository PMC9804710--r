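test_that("filter designs carry the right pieces", {
  a <- filter_design("A", disc_thickness_mm = 5)
  expect_true(is.na(a$square_side_cm))
  b <- filter_design("B", square_side_cm = 4, square_thickness_mm = 10)
  expect_true(is.na(b$disc_thickness_mm))
  c <- filter_design("C", disc_thickness_mm = 5, square_side_cm = 8,
                     square_thickness_mm = 5)
  expect_false(any(is.na(c(c$disc_thickness_mm, c$square_thickness_mm))))
  expect_error(build_scene(filter_design("B", square_side_cm = 13)),
               "larger than the collimator bore")
})

test_that("design A/B/C scenes resolve the documented probe points", {
  scA <- build_scene(filter_design("A", disc_thickness_mm = 5))
  # 5-mm disc fills the 12-cm bore exit
  expect_equal(locate(scA, c(0, 0, -0.25)), "lif_enriched")
  expect_equal(locate(scA, c(5.9, 0, -0.25)), "lif_enriched")
  expect_equal(locate(scA, c(0, 0, -0.75)), "air")

  scC <- build_scene(filter_design("C", disc_thickness_mm = 5,
                                   square_side_cm = 8, square_thickness_mm = 5))
  # on axis LiF through 10 mm, only 5 mm at (5.5, 0)
  expect_equal(locate(scC, c(0, 0, -0.25)), "lif_enriched")
  expect_equal(locate(scC, c(0, 0, -0.75)), "lif_enriched")
  expect_equal(locate(scC, c(5.5, 0, -0.25)), "lif_enriched")
  expect_equal(locate(scC, c(5.5, 0, -0.75)), "air")

  scB <- build_scene(filter_design("B", square_side_cm = 4,
                                   square_thickness_mm = 10))
  expect_equal(locate(scB, c(3, 0, -0.5)), "air")
  expect_equal(locate(scB, c(1, 0, -0.5)), "lif_enriched")

  expect_equal(locate(scA, c(0, 0, 10)), "water")
  expect_equal(locate(scA, c(0, 0, -5)), "air")
  expect_equal(locate(scA, c(10, 0, -5)), "lif_polyethylene")
  expect_equal(locate(scA, c(100, 0, 0)), "<escape>")
})

# plain-R re-implementation of region containment (oracle)
r_locate <- function(scene, p) {
  r <- scene$regions
  best <- NA_character_; bp <- -Inf
  for (i in seq_len(nrow(r))) {
    inside <- switch(r$type[i],
      box = p[1] >= r$p1[i] && p[1] <= r$p2[i] && p[2] >= r$p3[i] &&
        p[2] <= r$p4[i] && p[3] >= r$p5[i] && p[3] <= r$p6[i],
      cylinder = (p[1] - r$p1[i])^2 + (p[2] - r$p2[i])^2 <= r$p3[i]^2 &&
        p[3] >= r$p4[i] && p[3] <= r$p5[i],
      annulus = {
        rr <- (p[1] - r$p5[i])^2 + (p[2] - r$p6[i])^2
        rr >= r$p1[i]^2 && rr <= r$p2[i]^2 && p[3] >= r$p3[i] &&
          p[3] <= r$p4[i]
      })
    if (inside && r$priority[i] > bp) { bp <- r$priority[i]; best <- r$material[i] }
  }
  best
}

test_that("locate agrees with a brute-force containment oracle", {
  sc <- build_scene(filter_design("C", disc_thickness_mm = 5,
                                  square_side_cm = 8, square_thickness_mm = 5))
  set.seed(42)
  n <- 1e4
  pts <- cbind(runif(n, -20, 20), runif(n, -20, 20), runif(n, -10, 20))
  got <- locate(sc, pts)
  want <- vapply(seq_len(n), function(i) r_locate(sc, pts[i, ]), "")
  expect_identical(got, want)
})

test_that("distance to boundary is exact against a marching oracle", {
  sc <- build_scene(filter_design("A", disc_thickness_mm = 10))
  set.seed(7)
  for (trial in 1:15) {
    pos <- c(runif(1, -8, 8), runif(1, -8, 8), runif(1, -5, 15))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d <- distance_to_boundary(sc, pos, u)
    h <- 1e-4
    tgrid <- seq(h, min(d + 50 * h, 30), by = h)
    mats <- locate(sc, t(pos + outer(u, tgrid)))
    m0 <- locate(sc, pos + u * 1e-9)
    first <- which(mats != m0)[1]
    if (!is.na(first)) {
      expect_lt(abs(d - tgrid[first]), 2 * h)
    } else {
      expect_gt(d, max(tgrid) - 2 * h)
    }
  }
})

test_that("axial ray at the phantom face travels the full cube depth", {
  sc <- build_scene(NULL)
  expect_equal(distance_to_boundary(sc, c(0, 0, 1e-6), c(0, 0, 1)), 20,
               tolerance = 1e-6)
})

test_that("rays parallel to a face never return zero distance", {
  sc <- build_scene(NULL)
  d <- distance_to_boundary(sc, c(0, 0, 0), c(1, 0, 0))  # on the face plane
  expect_gt(d, 0)
})

test_that("traversed segment lengths add up to the total chord", {
  sc <- build_scene(filter_design("C", disc_thickness_mm = 5,
                                  square_side_cm = 8, square_thickness_mm = 5))
  set.seed(3)
  for (trial in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); u[3] <- abs(u[3])
    u <- u / sqrt(sum(u^2))
    pos <- c(runif(1, -3, 3), runif(1, -3, 3), -9.9)
    total <- 0
    p <- pos
    repeat {
      d <- distance_to_boundary(sc, p, u)
      if (d > 1e6) break
      total <- total + d
      p <- p + u * (d + 1e-9)
      if (locate(sc, p) == "<escape>") break
      if (total > 100) break
    }
    # chord from start to bounding-box exit along u
    bb <- sc$bbox
    tex <- min(vapply(1:3, function(ax) {
      if (abs(u[ax]) < 1e-14) return(Inf)
      max((bb[2 * ax - 1] - pos[ax]) / u[ax], (bb[2 * ax] - pos[ax]) / u[ax])
    }, 0))
    expect_equal(total, tex, tolerance = 1e-6)
  }
})
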