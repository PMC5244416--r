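# Shared fixtures. Expensive objects (generated movies + full analyses) are
# memoized per test run; everything is built in code, nothing on disk.
# Simulations use a reduced field (192-256 px at 0.3 um/px, ~20-45 frames)
# compared to the 512 px default, to keep the suite inside its time budget;
# the physical regime (5 s frames, ~18 um cell, 10 um sectors) is unchanged.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

small_cfg <- function(...) {
  defaults <- list(pixel_size_um = 0.3, image_shape = c(192L, 192L),
                   n_frames = 16L, cell_radius_um = 18, seed = 42L)
  do.call(sim_config, modifyList(defaults, list(...)))
}

test_pipeline_config <- function(...) {
  defaults <- list(pixel_size_um = 0.3, frame_interval_s = 5,
                   out_dir = tempfile("edgedyn"))
  do.call(pipeline_config, modifyList(defaults, list(...)))
}

# one protrusion pulse, analyzed end to end
smoke_analysis <- function() {
  memo("smoke", {
    cfg <- small_cfg(n_frames = 20L, seed = 3L, coloc_rho = 0.7,
                     boundary_kinematics = list(
                       kinematic_pulse("protrusion", 4, 16,
                                       center_arclength_um = 20, width_um = 30,
                                       speed_um_per_s = 0.15)))
    sim <- generate_cell_movie(cfg)
    res <- suppressMessages(analyze_movie(sim$movie, test_pipeline_config()))
    list(cfg = cfg, sim = sim, res = res)
  })
}

# a rasterized disk mask of radius r_um
disk_mask <- function(r_um, pixel_size_um = 0.25, pad_px = 8L) {
  n <- 2L * (ceiling(r_um / pixel_size_um) + pad_px) + 1L
  g <- pixel_grid_um(c(n, n), pixel_size_um)
  c0 <- (n - 1) / 2 * pixel_size_um
  mask <- sqrt((g$x - c0)^2 + (g$y - c0)^2) <= r_um
  structure(list(mask = mask, pixel_size_um = pixel_size_um, threshold = NA),
            class = "cell_mask")
}

# analytic circle boundary with exact perimeter P
circle_boundary <- function(perimeter_um, n = 720L, pixel_size_um = 0.25,
                            center = c(50, 50)) {
  r <- perimeter_um / (2 * pi)
  th <- 2 * pi * (seq_len(n) - 1) / n
  polygon_boundary(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
                   pixel_size_um = pixel_size_um, vertex_spacing_um = 0.25)
}

# fabricate an edge_heatmap from a plain matrix (velocity flavor by default)
fake_heatmap <- function(m, frame_interval_s = 5, flavor = "velocity") {
  edgedyn:::new_edge_heatmap(m, m, matrix(FALSE, nrow(m), ncol(m)),
                             frame_interval_s, flavor,
                             norm_max = max(abs(m)))
}

# planted-velocity field sampled at the recovered sector midpoints, per
# frame pair: used by the velocity-recovery checks
sample_truth_velocity <- function(res, truth) {
  nth <- length(truth$theta)
  v_true <- matrix(0, nrow(res$velocity_hm$raw), ncol(res$velocity_hm$raw))
  for (f in seq_len(ncol(v_true))) {
    b <- res$boundaries[[f]]
    mids <- edgedyn:::sector_midpoints(b)
    rel <- sweep(b$xy[mids, , drop = FALSE], 2, truth$center_um)
    th <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
    row <- round(th / (2 * pi) * nth) %% nth + 1
    v_true[, f] <- truth$velocity_um_per_s[row, f]
  }
  v_true
}

# circular ROI polygon (um) inside the simulated cell, centered on it:
# adhesion thresholds are meant to run inside a lamellipodium, not on the
# whole field, so tests pass an in-cell ROI
cell_roi <- function(cfg, r_um = 16, n = 90L) {
  cx <- (cfg$image_shape[2] - 1) / 2 * cfg$pixel_size_um
  cy <- (cfg$image_shape[1] - 1) / 2 * cfg$pixel_size_um
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r_um * cos(th), cy + r_um * sin(th))
}

# randomized planted-event movie used by the event-recovery checks: 1-2
# non-overlapping pulses with drift drawn from a fixed angle menu. Validity
# principle: a pulse's lateral travel plus width must stay well below the
# perimeter (else the drifting window laps the closed boundary and the
# planted event geometry is undefined). 45 deg pulses are therefore short
# (7 frames; shorter ones bias the moment angle) and run on a larger cell
# (24 um, 15 sectors) so travel + width <= 10 of 15 sectors.
random_event_movie <- function(seed) {
  set.seed(seed)
  angles <- c(0, 5, 15, 45)
  k <- sample(1:2, 1)
  ang <- sample(angles, k, replace = TRUE)
  kinds <- sample(c("protrusion", "retraction"), k, replace = TRUE)
  speeds <- runif(k, 0.1, 0.15)
  durs <- ifelse(ang == 45, 7L, sample(14:16, k, replace = TRUE))
  starts <- if (k == 1) 5L else c(5L, 26L)
  ends <- starts + durs
  radius <- if (any(ang == 45)) 24 else 18
  perim <- 2 * pi * radius
  centers <- runif(1, 0, perim) + (seq_len(k) - 1) * perim / 2
  # a traveling wave's heatmap signature is a thin streak whose moment axis
  # matches the drift slope; wide short blobs bias the axis upward, so the
  # steep (45 deg) pulses are planted narrower
  widths <- ifelse(ang == 45, 20, 30)
  pulses <- lapply(seq_len(k), function(i)
    kinematic_pulse(kinds[i], starts[i], ends[i],
                    center_arclength_um = centers[i], width_um = widths[i],
                    speed_um_per_s = speeds[i],
                    drift_sectors_per_frame = tan(ang[i] * pi / 180)))
  cfg <- sim_config(pixel_size_um = 0.3, image_shape = c(256L, 256L),
                    n_frames = 45L, cell_radius_um = radius, seed = seed,
                    boundary_kinematics = pulses)
  list(cfg = cfg,
       planted = data.frame(kind = kinds, angle_deg = ang,
                            duration_s = durs * 5, start_frame = starts))
}
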