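# Segmentation, boundary extraction, sector discretization, sector tracking.

make_disk_frame <- function(r_um, px = 0.25, level = 100, bg = 10, pad = 10L) {
  n <- 2L * (ceiling(r_um / px) + pad) + 1L
  g <- pixel_grid_um(c(n, n), px)
  c0 <- (n - 1) / 2 * px
  f <- matrix(bg, n, n)
  f[sqrt((g$x - c0)^2 + (g$y - c0)^2) <= r_um] <- level
  f
}

test_that("noiseless disk segments to within 2% of the analytic area", {
  f <- make_disk_frame(20, px = 0.25)
  m <- segment_cell(f, 0.25)
  expect_lt(abs(sum(m$mask) * 0.25^2 - pi * 400) / (pi * 400), 0.02)
})

test_that("segmentation failure modes are descriptive", {
  expect_error(segment_cell(matrix(5, 64, 64), 0.25, threshold = 10),
               "no cell found")
  two <- matrix(10, 101, 101)
  g <- pixel_grid_um(c(101L, 101L), 1)
  two[sqrt((g$x - 30)^2 + (g$y - 30)^2) <= 15] <- 100
  two[sqrt((g$x - 75)^2 + (g$y - 75)^2) <= 12] <- 100
  expect_error(segment_cell(two, 1), "multiple large components")
})

test_that("segmentation is deterministic and threshold-stable on clean input", {
  f <- make_disk_frame(15)
  expect_identical(segment_cell(f, 0.25), segment_cell(f, 0.25))
  m0 <- segment_cell(f, 0.25)
  thr <- m0$threshold
  for (d in c(0.9, 1.1)) {
    md <- segment_cell(f, 0.25, threshold = thr * d)
    expect_lt(mean(xor(md$mask, m0$mask)), 0.01)
  }
})

test_that("circle boundary: perimeter within 2%, normals within 5 deg of radial", {
  m <- disk_mask(15, pixel_size_um = 0.25)
  b <- extract_boundary(m)
  expect_lt(abs(b$perimeter_um - 2 * pi * 15) / (2 * pi * 15), 0.02)
  rel <- sweep(b$xy, 2, b$centroid_um)
  radial <- rel / sqrt(rowSums(rel^2))
  cosang <- rowSums(radial * b$normal)
  expect_gt(min(cosang), cos(5 * pi / 180))
})

test_that("square mask: normals at side midpoints align with the axes", {
  n <- 101L
  m <- matrix(FALSE, n, n); m[26:76, 26:76] <- TRUE
  b <- extract_boundary(structure(list(mask = m, pixel_size_um = 1),
                                  class = "cell_mask"))
  # at each side midpoint the normal should be axis-aligned
  mids <- list(c(51, 25, -1, 0), c(51, 77, 1, 0), c(25, 51, 0, -1), c(77, 51, 0, 1))
  for (md in mids) {
    # nearest boundary vertex to the (x, y) midpoint of this side
    d2 <- (b$xy[, 1] - (md[2] - 1))^2 + (b$xy[, 2] - (md[1] - 1))^2
    i <- which.min(d2)
    expect_gt(sum(b$normal[i, ] * md[3:4]), cos(5 * pi / 180))
  }
})

test_that("mirroring the mask mirrors the boundary", {
  m <- disk_mask(10, pixel_size_um = 0.5)
  m$mask[30, 10:20] <- FALSE   # break symmetry
  m$mask <- fill_holes(m$mask)
  b1 <- extract_boundary(m)
  m2 <- m; m2$mask <- m$mask[, ncol(m$mask):1]
  b2 <- extract_boundary(m2)
  w <- (ncol(m$mask) - 1) * 0.5
  # mirrored x coordinates cover the same set of positions
  expect_equal(sort(round(w - b2$xy[, 1], 3)), sort(round(b1$xy[, 1], 3)),
               tolerance = 0.05)
  expect_equal(b1$perimeter_um, b2$perimeter_um, tolerance = 1e-4)
})

test_that("degenerate masks are rejected", {
  m <- matrix(FALSE, 32, 32); m[16, 16] <- TRUE
  expect_error(extract_boundary(structure(list(mask = m, pixel_size_um = 1),
                                          class = "cell_mask")),
               "degenerate")
})

test_that("sector discretization follows N = round(P / L) with exact division", {
  b100 <- circle_boundary(100)
  s <- discretize_sectors(b100, 10)
  expect_equal(attr(s, "n_sectors"), 10L)
  lens <- tabulate(s$sector_id) * (s$perimeter_um / length(s$sector_id))
  expect_equal(lens, rep(10, 10), tolerance = 0.05)

  b104 <- circle_boundary(104)
  s104 <- discretize_sectors(b104, 10)
  expect_equal(attr(s104, "n_sectors"), 10L)
  expect_equal(attr(s104, "sector_length_um"), 10.4, tolerance = 0.01)

  # conservation: per-sector arclengths sum to the perimeter
  expect_equal(sum(tabulate(s104$sector_id)) * s104$perimeter_um /
                 length(s104$sector_id),
               s104$perimeter_um, tolerance = 1e-9)
  expect_error(discretize_sectors(circle_boundary(15), 10), "perimeter")
})

test_that("track_sectors: identical boundaries give zero displacement", {
  b <- discretize_sectors(circle_boundary(100), 10)
  d <- track_sectors(b, b)
  expect_true(all(abs(d$v_normal_um) < 1e-9))
  expect_true(all(!d$missing))
})

test_that("track_sectors: radial growth r -> r + delta gives d.n = delta", {
  r <- 100 / (2 * pi)
  b1 <- discretize_sectors(circle_boundary(2 * pi * r), 10)
  b2 <- discretize_sectors(circle_boundary(2 * pi * (r + 0.8)), 10,
                           n_sectors = attr(b1, "n_sectors"))
  d <- track_sectors(b1, b2)
  expect_true(all(abs(d$v_normal_um - 0.8) / 0.8 < 0.05))
})

test_that("track_sectors: rigid translation projects as u.n per sector", {
  # under normal-ray correspondence the measured displacement is the normal
  # component of the shift, d = (u.n) n, so each sector reports u.n (and the
  # mean over a closed convex boundary is u/2, not u)
  th <- 2 * pi * (0:719) / 720
  r <- 12
  xy1 <- cbind(40 + r * cos(th), 40 + r * sin(th))
  u <- c(0.7, -0.4)
  b1 <- discretize_sectors(polygon_boundary(xy1, 0.25), 10)
  b2 <- discretize_sectors(polygon_boundary(sweep(xy1, 2, -u), 0.25), 10,
                           n_sectors = attr(b1, "n_sectors"))
  d <- track_sectors(b1, b2)
  expected <- d$nx * u[1] + d$ny * u[2]
  expect_equal(d$v_normal_um, expected, tolerance = 0.05)
  expect_equal(mean(d$dx_um), u[1] / 2, tolerance = 0.1)
  expect_equal(mean(d$dy_um), u[2] / 2, tolerance = 0.1)
})

test_that("track_sectors flags unmatched sectors instead of zeroing them", {
  b1 <- discretize_sectors(circle_boundary(100, center = c(50, 50)), 10)
  b2 <- discretize_sectors(circle_boundary(100, center = c(90, 50)), 10)
  d <- track_sectors(b1, b2, search_um = 5)
  expect_true(any(d$missing))
  expect_true(all(!is.na(d$v_normal_um)))  # fallback recorded, but flagged
  expect_error(track_sectors(b1, discretize_sectors(circle_boundary(100), 10,
                                                    n_sectors = 12L)),
               "sector counts differ")
})

test_that("rotation by 90 deg preserves perimeter and sector arclengths", {
  m <- disk_mask(10, pixel_size_um = 0.5)
  m$mask[35:40, 20:25] <- TRUE   # asymmetric lobe
  m$mask <- fill_holes(m$mask)
  b1 <- discretize_sectors(extract_boundary(m), 10)
  mr <- m; mr$mask <- t(m$mask)[ncol(m$mask):1, ]
  b2 <- discretize_sectors(extract_boundary(mr), 10)
  expect_equal(b1$perimeter_um, b2$perimeter_um, tolerance = 0.01)
  expect_equal(attr(b1, "n_sectors"), attr(b2, "n_sectors"))
})

test_that("halving pixel size changes the perimeter estimate by < 2%", {
  b1 <- extract_boundary(disk_mask(12, pixel_size_um = 0.5))
  b2 <- extract_boundary(disk_mask(12, pixel_size_um = 0.25))
  expect_lt(abs(b1$perimeter_um - b2$perimeter_um) / b2$perimeter_um, 0.02)
})
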