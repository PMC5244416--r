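# Synthetic two-channel live-cell movie generator with planted ground truth.
#
# The cell boundary is modeled as a star-convex radial function r(theta, t)
# around a fixed centroid: kinematic pulses add or remove radius inside a
# (possibly laterally drifting) arclength window, which cannot self-intersect
# and keeps the planted normal velocities analytically known. The mask is
# rasterized from r(theta), and channel intensities inside the edge band are
# drawn from a shared latent Gaussian field with mixing weights chosen so the
# final pixel correlation (including camera noise) hits the configured rho.

N_THETA <- 720L

# piecewise profile of a pulse window on the circle of base arclengths:
# 1 in the core, cosine ramp over `taper` um at each edge, 0 outside.
pulse_profile <- function(arc, center, width, perimeter, taper = 2) {
  d <- abs(((arc - center + perimeter / 2) %% perimeter) - perimeter / 2)
  half <- width / 2
  taper <- min(taper, half / 2)
  w <- numeric(length(d))
  w[d <= half - taper] <- 1
  ramp <- d > half - taper & d < half + taper
  w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - (half - taper)) / (2 * taper)))
  w
}

# radius matrix r[theta, frame] for a config; errors on degenerate geometry
simulate_radius <- function(cfg) {
  theta <- 2 * pi * (seq_len(N_THETA) - 1) / N_THETA
  r0 <- cfg$cell_radius_um
  perim0 <- 2 * pi * r0
  arc <- theta * r0
  r <- matrix(r0, N_THETA, cfg$n_frames)
  for (f in 2:cfg$n_frames) {
    dr <- numeric(N_THETA)
    for (p in cfg$boundary_kinematics) {
      if (f <= p$start_frame || f > p$end_frame) next
      drift_um <- p$drift_sectors_per_frame * cfg$sector_length_um
      center <- p$center_arclength_um + drift_um * (f - p$start_frame)
      sgn <- if (p$kind == "protrusion") 1 else -1
      dr <- dr + sgn * p$speed_um_per_s * cfg$frame_interval_s *
        pulse_profile(arc, center, p$width_um, perim0)
    }
    r[, f] <- r[, f - 1] + dr
  }
  extent <- (cfg$image_shape - 1) * cfg$pixel_size_um
  if (any(r < 2))
    stop("simulate: pulse geometry collapses the boundary (r < 2 um); ",
         "reduce retraction speed or duration")
  if (any(r > min(extent) / 2 - 2 * cfg$pixel_size_um))
    stop("simulate: pulse geometry exceeds the image field; ",
         "enlarge image_shape or reduce protrusion")
  list(theta = theta, arc = arc, r = r, perim0 = perim0)
}

# interpolate r(theta) at arbitrary angles (periodic)
interp_radius <- function(theta_grid, r_col, theta_query) {
  n <- length(theta_grid)
  step <- 2 * pi / n
  tq <- theta_query %% (2 * pi)
  i0 <- floor(tq / step)
  frac <- tq / step - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  r_col[i0] * (1 - frac) + r_col[i1] * frac
}

#' Generate a synthetic two-channel single-cell movie with ground truth
#'
#' Renders a simply-connected cell whose boundary deforms according to the
#' pulses in `cfg$boundary_kinematics`. Channel 1 (marker) and channel 2
#' (actin reporter) share a correlated fluctuation field inside the 2 um edge
#' band so that the band pixel correlation equals `cfg$coloc_rho` (locally
#' overridden by `cfg$coloc_patches`).
#'
#' @param cfg a [sim_config()].
#' @return list with `movie` (class `edge_movie`: channel arrays `ch1`,
#'   `ch2` of dim rows x cols x frames, plus calibration) and `truth`
#'   (class `sim_ground_truth`: per-frame boundary polygons, per-sector true
#'   normal velocities, planted event and band-correlation tables).
#' @export
generate_cell_movie <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    geo <- simulate_radius(cfg)
    ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
    px <- cfg$pixel_size_um
    cx <- (nx - 1) / 2 * px; cy <- (ny - 1) / 2 * px
    grid <- pixel_grid_um(cfg$image_shape, px)
    gx <- grid$x - cx; gy <- grid$y - cy
    rho_px <- sqrt(gx^2 + gy^2)
    theta_px <- atan2(gy, gx) %% (2 * pi)

    # sector geometry of the resting cell, anchored at theta = 0 (+x ray)
    n_sectors <- max(4L, as.integer(round(geo$perim0 / cfg$sector_length_um)))
    sector_of_arc <- function(arc)
      (floor(arc / (geo$perim0 / n_sectors)) %% n_sectors) + 1L

    # per-sector, per-frame target correlation
    band_rho <- matrix(cfg$coloc_rho, n_sectors, cfg$n_frames)
    for (patch in cfg$coloc_patches)
      band_rho[patch$sectors, patch$frames] <- patch$rho

    infl <- (cfg$band_amplitude^2 + cfg$noise_sd^2) / cfg$band_amplitude^2
    ch1 <- array(0, dim = c(ny, nx, cfg$n_frames))
    ch2 <- array(0, dim = c(ny, nx, cfg$n_frames))
    for (f in seq_len(cfg$n_frames)) {
      r_at <- interp_radius(geo$theta, geo$r[, f], theta_px)
      inside <- rho_px <= r_at
      base <- matrix(cfg$background_level, ny, nx)
      base[inside] <- cfg$cell_level
      g <- base; rr <- base
      band <- inside & (r_at - rho_px <= cfg$band_depth_um)
      nb <- sum(band)
      if (nb > 0) {
        rho_eff <- band_rho[sector_of_arc(theta_px[band] * cfg$cell_radius_um), f] * infl
        a <- sqrt(abs(rho_eff)); b <- sqrt(1 - abs(rho_eff))
        z <- rnorm(nb); e1 <- rnorm(nb); e2 <- rnorm(nb)
        g[band] <- g[band] + cfg$band_amplitude * (a * z + b * e1)
        rr[band] <- rr[band] + cfg$band_amplitude * (sign(rho_eff) * a * z + b * e2)
      }
      if (cfg$noise_sd > 0) {
        g <- g + rnorm(ny * nx, sd = cfg$noise_sd)
        rr <- rr + rnorm(ny * nx, sd = cfg$noise_sd)
      }
      ch1[, , f] <- g
      ch2[, , f] <- rr
    }

    # ground truth: analytic boundary and normal velocities
    boundary <- lapply(seq_len(cfg$n_frames), function(f)
      cbind(x_um = cx + geo$r[, f] * cos(geo$theta),
            y_um = cy + geo$r[, f] * sin(geo$theta)))
    # normal velocity: radial rate corrected by the angle between the radial
    # direction and the boundary normal, cos(psi) = r / sqrt(r^2 + (dr/dtheta)^2)
    dtheta <- 2 * pi / N_THETA
    v_n <- matrix(0, N_THETA, cfg$n_frames - 1L)
    for (f in seq_len(cfg$n_frames - 1L)) {
      rmid <- (geo$r[, f] + geo$r[, f + 1]) / 2
      drdth <- (rmid[c(2:N_THETA, 1)] - rmid[c(N_THETA, 1:(N_THETA - 1))]) / (2 * dtheta)
      cospsi <- rmid / sqrt(rmid^2 + drdth^2)
      v_n[, f] <- (geo$r[, f + 1] - geo$r[, f]) / cfg$frame_interval_s * cospsi
    }
    sector_idx <- sector_of_arc(geo$arc)
    sector_velocity <- t(vapply(seq_len(n_sectors), function(s)
      colMeans(v_n[sector_idx == s, , drop = FALSE]),
      numeric(cfg$n_frames - 1L)))

    events <- do.call(rbind, lapply(cfg$boundary_kinematics, function(p)
      data.frame(kind = p$kind, start_frame = p$start_frame,
                 end_frame = p$end_frame,
                 duration_s = (p$end_frame - p$start_frame) * cfg$frame_interval_s,
                 angle_deg = abs(atan(p$drift_sectors_per_frame)) * 180 / pi,
                 center_arclength_um = p$center_arclength_um,
                 width_um = p$width_um, speed_um_per_s = p$speed_um_per_s,
                 stringsAsFactors = FALSE)))
    if (is.null(events))
      events <- data.frame(kind = character(), start_frame = integer(),
                           end_frame = integer(), duration_s = numeric(),
                           angle_deg = numeric(), center_arclength_um = numeric(),
                           width_um = numeric(), speed_um_per_s = numeric())

    movie <- structure(list(ch1 = ch1, ch2 = ch2,
                            pixel_size_um = px,
                            frame_interval_s = cfg$frame_interval_s,
                            channel_names = c("marker", "actin")),
                       class = "edge_movie")
    truth <- structure(list(theta = geo$theta, radius_um = geo$r,
                            boundary = boundary, center_um = c(cx, cy),
                            velocity_um_per_s = v_n,
                            theta_sector = sector_idx,
                            sector_velocity_um_per_s = sector_velocity,
                            n_sectors = n_sectors, band_rho = band_rho,
                            events = events, config = cfg),
                       class = "sim_ground_truth")
    list(movie = movie, truth = truth)
  })
}

#' Generate a single adhesion (paxillin-like) frame with planted puncta
#'
#' Renders elliptical puncta inside a circular cell mask. Overlapping sites
#' are reported in the ground-truth table as one merged object with union
#' area, matching what any object-based detector can recover.
#'
#' @param cfg a [sim_config()] with non-empty `adhesion_sites`.
#' @return list with `frame` (intensity matrix), `cell_mask`, `truth`
#'   (data.frame: one row per merged object with pixel-exact area, longest
#'   axis from second moments, centroid, and centroid-to-membrane distance),
#'   and `site_label` (integer matrix of rendered site support).
#' @export
generate_adhesion_frame <- function(cfg) {
  validate_sim_config(cfg)
  if (!length(cfg$adhesion_sites))
    stop("generate_adhesion_frame: adhesion_sites is empty")
  with_seed(cfg$seed + 1L, {
    ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
    px <- cfg$pixel_size_um
    cx <- (nx - 1) / 2 * px; cy <- (ny - 1) / 2 * px
    grid <- pixel_grid_um(cfg$image_shape, px)
    gx <- grid$x - cx; gy <- grid$y - cy
    cell <- sqrt(gx^2 + gy^2) <= cfg$cell_radius_um

    support <- matrix(FALSE, ny, nx)
    frame <- matrix(cfg$background_level, ny, nx)
    frame[cell] <- cfg$cell_level
    for (s in cfg$adhesion_sites) {
      reach <- sqrt(sum(s$center_um^2)) + max(s$semi_axes_um)
      if (reach > cfg$cell_radius_um)
        stop("generate_adhesion_frame: site at (",
             paste(signif(s$center_um, 3), collapse = ", "),
             ") um extends outside the cell mask")
      th <- s$angle_deg * pi / 180
      ux <- (gx - s$center_um[1]) * cos(th) + (gy - s$center_um[2]) * sin(th)
      uy <- -(gx - s$center_um[1]) * sin(th) + (gy - s$center_um[2]) * cos(th)
      inside <- (ux / s$semi_axes_um[1])^2 + (uy / s$semi_axes_um[2])^2 <= 1
      frame[inside] <- frame[inside] + s$intensity
      support <- support | inside
    }
    if (cfg$noise_sd > 0)
      frame <- frame + matrix(rnorm(ny * nx, sd = cfg$noise_sd), ny, nx)

    lab <- label_components(support, 8L)
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    truth <- do.call(rbind, lapply(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      m <- region_moments(w[, 1], w[, 2], px)
      dist <- cfg$cell_radius_um -
        sqrt((m$centroid_x - cx)^2 + (m$centroid_y - cy)^2)
      data.frame(site_id = id, area_um2 = nrow(w) * px^2,
                 major_axis_um = m$major_axis_um,
                 centroid_x_um = m$centroid_x, centroid_y_um = m$centroid_y,
                 distance_to_membrane_um = dist)
    }))
    list(frame = frame, cell_mask = cell, truth = truth, site_label = lab)
  })
}

# area-normalized second-moment morphometry of a pixel region
# (major axis length = full length of the longest axis, 4*sqrt(lambda_max),
# the standard ellipse-equivalent convention)
region_moments <- function(rows, cols, pixel_size_um) {
  x <- (cols - 1) * pixel_size_um
  y <- (rows - 1) * pixel_size_um
  mx <- mean(x); my <- mean(y)
  n <- length(x)
  cxx <- sum((x - mx)^2) / n
  cyy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  lam_max <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
  list(centroid_x = mx, centroid_y = my,
       major_axis_um = 4 * sqrt(lam_max),
       orientation_deg = 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi)
}

#' Generate correlated-random-walk cell tracks with ground truth
#'
#' Headings evolve as a wrapped Gaussian random walk with turning-angle SD
#' `(1 - track_persistence) * pi`, so persistence 1 gives perfectly straight
#' tracks (meandering index 1) and persistence 0 gives near-Brownian motion.
#'
#' @param cfg a [sim_config()].
#' @param n_tracks number of tracks (>= 1).
#' @return list with `tracks` (data.frame: track_id, frame, x_um, y_um) and
#'   `truth` (data.frame of planted meandering indices).
#' @export
generate_tracks <- function(cfg, n_tracks = 10L) {
  validate_sim_config(cfg)
  if (n_tracks < 1L) stop("generate_tracks: n_tracks must be >= 1")
  with_seed(cfg$seed + 2L, {
    sd_turn <- (1 - cfg$track_persistence) * pi
    out <- vector("list", n_tracks)
    mi <- numeric(n_tracks)
    for (k in seq_len(n_tracks)) {
      head0 <- runif(1, 0, 2 * pi)
      turns <- if (cfg$n_frames > 2L)
        rnorm(cfg$n_frames - 2L, sd = sd_turn) else numeric(0)
      headings <- head0 + cumsum(c(0, turns))
      dx <- cfg$track_step_um * cos(headings)
      dy <- cfg$track_step_um * sin(headings)
      x <- cumsum(c(0, dx)); y <- cumsum(c(0, dy))
      out[[k]] <- data.frame(track_id = k, frame = seq_len(cfg$n_frames),
                             x_um = x, y_um = y)
      disp <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
      path <- sum(sqrt(dx^2 + dy^2))
      mi[k] <- if (path > 0) disp / path else NA_real_
    }
    list(tracks = do.call(rbind, out),
         truth = data.frame(track_id = seq_len(n_tracks),
                            meandering_index = mi))
  })
}

#' Generate a scratch-wound mask series with ground truth
#'
#' Binary cell-occupancy masks with a central vertical cell-free stripe whose
#' width shrinks linearly at `wound_closure_rate` (fraction of initial area
#' per hour) until it vanishes.
#'
#' @param cfg a [sim_config()].
#' @return list with `masks` (logical array rows x cols x frames; TRUE =
#'   cells), `truth` (data.frame: frame, t_h, wound area um^2 from pixel
#'   counts, percent closed).
#' @export
generate_wound_series <- function(cfg) {
  validate_sim_config(cfg)
  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  px <- cfg$pixel_size_um
  xc <- (nx - 1) / 2 * px
  xg <- (seq_len(nx) - 1) * px
  t_h <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_s / 3600
  w0 <- cfg$wound_width_um
  if (w0 >= (nx - 4) * px)
    stop("generate_wound_series: wound_width_um wider than the image")
  masks <- array(TRUE, dim = c(ny, nx, cfg$n_frames))
  area <- numeric(cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    w <- w0 * max(0, 1 - cfg$wound_closure_rate * t_h[f])
    stripe <- abs(xg - xc) < w / 2
    masks[, stripe, f] <- FALSE
    area[f] <- sum(stripe) * ny * px^2
  }
  pct <- if (area[1] > 0) pmax(0, 100 * (area[1] - area) / area[1])
         else rep(0, cfg$n_frames)
  truth <- data.frame(frame = seq_len(cfg$n_frames), t_h = t_h,
                      wound_area_um2 = area, percent_closed = pct)
  list(masks = masks, truth = truth)
}
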