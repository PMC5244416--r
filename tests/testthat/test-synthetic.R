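# Synthetic-data generator: planted kinematics, band correlation, adhesion
# frames, tracks, wound series, determinism.

test_that("static noiseless cell gives identical frames and zero velocities", {
  cfg <- small_cfg(n_frames = 4L, noise_sd = 0, band_amplitude = 0,
                   coloc_rho = 0)
  sim <- generate_cell_movie(cfg)
  for (f in 2:4) {
    expect_identical(sim$movie$ch1[, , f], sim$movie$ch1[, , 1])
    expect_identical(sim$movie$ch2[, , f], sim$movie$ch2[, , 1])
  }
  expect_true(all(sim$truth$velocity_um_per_s == 0))
  expect_true(all(sim$truth$sector_velocity_um_per_s == 0))
})

test_that("a drift-free pulse plants angle 0 and duration (end-start)*dt", {
  cfg <- small_cfg(boundary_kinematics = list(
    kinematic_pulse("protrusion", 3, 11, center_arclength_um = 40,
                    width_um = 25, speed_um_per_s = 0.1)))
  sim <- generate_cell_movie(cfg)
  ev <- sim$truth$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$angle_deg, 0)
  expect_equal(ev$duration_s, (11 - 3) * cfg$frame_interval_s)
  # planted core velocity equals the nominal speed
  expect_equal(max(sim$truth$velocity_um_per_s), 0.1, tolerance = 1e-12)
})

test_that("band pixel correlation hits coloc_rho (direct correlation oracle)", {
  cfg <- small_cfg(n_frames = 2L, coloc_rho = 0.8, seed = 1L)
  sim <- generate_cell_movie(cfg)
  # identify band pixels from the analytic geometry (radius - rho <= depth)
  g <- pixel_grid_um(cfg$image_shape, cfg$pixel_size_um)
  gx <- g$x - sim$truth$center_um[1]; gy <- g$y - sim$truth$center_um[2]
  rho <- sqrt(gx^2 + gy^2)
  r_at <- cfg$cell_radius_um   # static circle
  band <- rho <= r_at & (r_at - rho) <= cfg$band_depth_um
  expect_gte(sum(band), 500)
  for (f in 1:2) {
    r_obs <- cor(sim$movie$ch1[, , f][band], sim$movie$ch2[, , f][band])
    expect_lt(abs(r_obs - 0.8), 0.05)
  }
})

test_that("negative coloc_rho is honored", {
  cfg <- small_cfg(n_frames = 2L, coloc_rho = -0.6, seed = 8L)
  sim <- generate_cell_movie(cfg)
  g <- pixel_grid_um(cfg$image_shape, cfg$pixel_size_um)
  rho <- sqrt((g$x - sim$truth$center_um[1])^2 + (g$y - sim$truth$center_um[2])^2)
  band <- rho <= cfg$cell_radius_um & (cfg$cell_radius_um - rho) <= 2
  expect_lt(abs(cor(sim$movie$ch1[, , 1][band], sim$movie$ch2[, , 1][band]) + 0.6),
            0.05)
})

test_that("same config reproduces bit-identical movies and ground truth", {
  cfg <- small_cfg(n_frames = 4L, coloc_rho = 0.5,
                   boundary_kinematics = list(
                     kinematic_pulse("retraction", 1, 3, 30, 20, 0.1)))
  a <- generate_cell_movie(cfg)
  b <- generate_cell_movie(cfg)
  expect_identical(a$movie, b$movie)
  expect_identical(a$truth, b$truth)
})

test_that("doubling noise_sd leaves ground-truth tables unchanged", {
  base <- small_cfg(n_frames = 4L, boundary_kinematics = list(
    kinematic_pulse("protrusion", 1, 3, 10, 20, 0.1)))
  noisy <- small_cfg(n_frames = 4L, noise_sd = base$noise_sd * 2,
                     boundary_kinematics = base$boundary_kinematics)
  a <- generate_cell_movie(base)$truth
  b <- generate_cell_movie(noisy)$truth
  expect_identical(a$velocity_um_per_s, b$velocity_um_per_s)
  expect_identical(a$events, b$events)
  expect_identical(a$boundary, b$boundary)
})

test_that("degenerate pulse geometry is rejected with a descriptive error", {
  expect_error(generate_cell_movie(small_cfg(n_frames = 40L,
    boundary_kinematics = list(kinematic_pulse("retraction", 1, 39, 0,
                                               width_um = 200,
                                               speed_um_per_s = 0.5)))),
    "collapses")
  expect_error(generate_cell_movie(small_cfg(n_frames = 40L,
    boundary_kinematics = list(kinematic_pulse("protrusion", 1, 39, 0,
                                               width_um = 40,
                                               speed_um_per_s = 0.5)))),
    "exceeds the image")
})

test_that("config validation rejects bad fields", {
  expect_error(sim_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(coloc_rho = 1.2), "coloc_rho")
  expect_error(kinematic_pulse("protrusion", 5, 5, 0, 10, 0.1), "start_frame")
  expect_error(kinematic_pulse("protrusion", 1, 5, 0, -1, 0.1), "width_um")
  # unreachable correlation after camera noise
  expect_error(sim_config(coloc_rho = 0.999, band_amplitude = 1, noise_sd = 5),
               "unreachable")
})

test_that("self-consistency: velocity operator on ground-truth boundaries
          recovers planted speeds within 10%", {
  cfg <- small_cfg(n_frames = 14L, boundary_kinematics = list(
    kinematic_pulse("protrusion", 2, 12, center_arclength_um = 30,
                    width_um = 30, speed_um_per_s = 0.12)))
  sim <- generate_cell_movie(cfg)
  bounds <- lapply(sim$truth$boundary, function(xy)
    discretize_sectors(polygon_boundary(xy, cfg$pixel_size_um), 10,
                       n_sectors = sim$truth$n_sectors))
  disp <- lapply(seq_len(13L), function(f)
    track_sectors(bounds[[f]], bounds[[f + 1]]))
  hm <- build_velocity_heatmap(disp, cfg$frame_interval_s)
  v_rec <- hm$raw / cfg$frame_interval_s
  # compare where the planted per-sector speed is at full amplitude
  core <- abs(sim$truth$sector_velocity_um_per_s - 0.12) < 0.005
  expect_gt(sum(core), 10)
  rel <- (v_rec[core] - sim$truth$sector_velocity_um_per_s[core]) /
    sim$truth$sector_velocity_um_per_s[core]
  expect_lt(max(abs(rel)), 0.10)
})

test_that("adhesion frame: planted circle has exact distance and ~2 um axis", {
  cfg <- small_cfg(noise_sd = 0, adhesion_sites = list(
    adhesion_site_spec(center_um = c(15, 0), semi_axes_um = c(1, 1))))
  gt <- generate_adhesion_frame(cfg)
  expect_equal(nrow(gt$truth), 1L)
  expect_equal(gt$truth$distance_to_membrane_um, 18 - 15)
  expect_equal(gt$truth$major_axis_um, 2, tolerance = 0.1)
  expect_equal(gt$truth$area_um2, pi, tolerance = 0.1)
})

test_that("overlapping adhesion sites merge into one union object", {
  cfg <- small_cfg(noise_sd = 0, adhesion_sites = list(
    adhesion_site_spec(c(5, 0), c(1.5, 1)),
    adhesion_site_spec(c(6.5, 0), c(1.5, 1))))
  gt <- generate_adhesion_frame(cfg)
  expect_equal(nrow(gt$truth), 1L)
  # union is smaller than the sum of the two ellipse areas
  expect_lt(gt$truth$area_um2, 2 * pi * 1.5)
  expect_gt(gt$truth$area_um2, pi * 1.5)
})

test_that("adhesion frame rejects sites outside the cell and is deterministic", {
  expect_error(generate_adhesion_frame(small_cfg(adhesion_sites = list(
    adhesion_site_spec(c(17.5, 0), c(1, 1))))), "outside the cell")
  expect_error(generate_adhesion_frame(small_cfg()), "empty")
  cfg <- small_cfg(adhesion_sites = lapply(1:10, function(i)
    adhesion_site_spec(c(10 * cos(i), 10 * sin(i)), c(0.8, 0.5), angle_deg = 20 * i)))
  expect_identical(generate_adhesion_frame(cfg), generate_adhesion_frame(cfg))
})

test_that("tracks: persistence 1 gives straight tracks; ground truth matches
          a direct displacement/distance recomputation", {
  cfg <- small_cfg(track_persistence = 1, n_frames = 20L)
  tr <- generate_tracks(cfg, n_tracks = 3L)
  expect_equal(tr$truth$meandering_index, rep(1, 3), tolerance = 1e-12)

  cfg2 <- small_cfg(track_persistence = 0.5, n_frames = 100L, seed = 7L)
  tr2 <- generate_tracks(cfg2, n_tracks = 5L)
  for (id in 1:5) {
    p <- tr2$tracks[tr2$tracks$track_id == id, ]
    disp <- sqrt(diff(range(0, p$x_um[c(1, nrow(p))]))^2 +
                 diff(range(0, p$y_um[c(1, nrow(p))]))^2)
    disp <- sqrt((p$x_um[nrow(p)] - p$x_um[1])^2 + (p$y_um[nrow(p)] - p$y_um[1])^2)
    path <- sum(sqrt(diff(p$x_um)^2 + diff(p$y_um)^2))
    expect_equal(tr2$truth$meandering_index[id], disp / path, tolerance = 1e-12)
  }
})

test_that("wound series: rate 0 is constant; closure completes and areas are
          pixel counts", {
  cfg0 <- small_cfg(wound_closure_rate = 0, frame_interval_s = 480,
                    n_frames = 6L, wound_width_um = 20)
  w0 <- generate_wound_series(cfg0)
  expect_true(all(w0$truth$wound_area_um2 == w0$truth$wound_area_um2[1]))
  expect_true(all(w0$truth$percent_closed == 0))

  cfg1 <- small_cfg(wound_closure_rate = 1.5, frame_interval_s = 480,
                    n_frames = 8L, wound_width_um = 20)
  w1 <- generate_wound_series(cfg1)
  done <- w1$truth$t_h >= 1 / 1.5
  expect_true(all(w1$truth$percent_closed[done] == 100))
  expect_true(all(w1$truth$wound_area_um2[done] == 0))
  # oracle: areas equal pixel counts of the cell-free region
  for (f in seq_len(cfg1$n_frames)) {
    expect_equal(w1$truth$wound_area_um2[f],
                 sum(!w1$masks[, , f]) * cfg1$pixel_size_um^2)
  }
})
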