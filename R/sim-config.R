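#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-movie generator. The
#' defaults emulate the membrane/colocalization imaging regime of the study
#' system: spinning-disk confocal at high magnification (0.2 um/px), one
#' frame every 5 s for up to 5 min. Other regimes (paxillin: 30 s frames for
#' up to 30 min; scratch wound: 8 min frames for 21 h) are reached by
#' overriding `frame_interval_s` / `n_frames` / `pixel_size_um`.
#'
#' @param pixel_size_um physical pixel pitch, um/pixel (> 0). Default 0.2,
#'   typical of a 63x confocal; the imaging system reports magnification, not
#'   pixel pitch, so this is a documented default rather than a derived value.
#' @param frame_interval_s seconds between frames (> 0).
#' @param n_frames number of frames (>= 2).
#' @param image_shape integer c(rows, cols) in pixels.
#' @param seed integer seed; the same config (including seed) reproduces
#'   bit-identical movies and ground truth.
#' @param cell_radius_um radius of the resting (circular) cell.
#' @param boundary_kinematics list of [kinematic_pulse()] objects.
#' @param coloc_rho target Pearson correlation of the two channels inside the
#'   2 um edge band, in \[-1, 1\].
#' @param coloc_patches optional list of patches overriding `coloc_rho`
#'   locally; each a list with `sectors` (integer vector, 1-based),
#'   `frames` (integer vector) and `rho`.
#' @param background_level mean intensity outside the cell.
#' @param cell_level mean intensity inside the cell (both channels).
#' @param band_amplitude SD of the correlated fluctuation field added in the
#'   edge band; the mixing weights are chosen analytically so that the final
#'   pixel correlation (after adding `noise_sd` camera noise) equals
#'   `coloc_rho` (see vignette).
#' @param noise_sd SD of i.i.d. Gaussian camera noise added everywhere.
#' @param band_depth_um depth of the correlated edge band (matches the 2 um
#'   analysis band).
#' @param sector_length_um nominal boundary sector length used to convert a
#'   pulse's lateral drift (sectors/frame) into arclength drift.
#' @param adhesion_sites list of [adhesion_site_spec()] objects (used by
#'   [generate_adhesion_frame()]).
#' @param track_persistence directional persistence of simulated tracks in
#'   \[0, 1\]; 1 = perfectly straight.
#' @param track_step_um step length per frame for simulated tracks.
#' @param wound_closure_rate fraction of the initial wound area closed per
#'   hour (>= 0).
#' @param wound_width_um initial width of the cell-free stripe.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pixel_size_um = 0.2,
                       frame_interval_s = 5,
                       n_frames = 60L,
                       image_shape = c(512L, 512L),
                       seed = 1L,
                       cell_radius_um = 20,
                       boundary_kinematics = list(),
                       coloc_rho = 0,
                       coloc_patches = list(),
                       background_level = 10,
                       cell_level = 100,
                       band_amplitude = 20,
                       noise_sd = 2,
                       band_depth_um = 2,
                       sector_length_um = 10,
                       adhesion_sites = list(),
                       track_persistence = 0.5,
                       track_step_um = 1,
                       wound_closure_rate = 0.1,
                       wound_width_um = 300) {
  cfg <- list(
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), image_shape = as.integer(image_shape),
    seed = as.integer(seed), cell_radius_um = cell_radius_um,
    boundary_kinematics = boundary_kinematics, coloc_rho = coloc_rho,
    coloc_patches = coloc_patches, background_level = background_level,
    cell_level = cell_level, band_amplitude = band_amplitude,
    noise_sd = noise_sd, band_depth_um = band_depth_um,
    sector_length_um = sector_length_um, adhesion_sites = adhesion_sites,
    track_persistence = track_persistence, track_step_um = track_step_um,
    wound_closure_rate = wound_closure_rate, wound_width_um = wound_width_um
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    stop("sim_config: pixel_size_um must be > 0")
  if (!is.numeric(cfg$frame_interval_s) || cfg$frame_interval_s <= 0)
    stop("sim_config: frame_interval_s must be > 0")
  if (cfg$n_frames < 2L) stop("sim_config: n_frames must be >= 2")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 16L))
    stop("sim_config: image_shape must be c(rows, cols), each >= 16")
  if (abs(cfg$coloc_rho) > 1) stop("sim_config: |coloc_rho| must be <= 1")
  if (cfg$wound_closure_rate < 0)
    stop("sim_config: wound_closure_rate must be >= 0")
  if (cfg$track_persistence < 0 || cfg$track_persistence > 1)
    stop("sim_config: track_persistence must be in [0, 1]")
  for (p in cfg$boundary_kinematics) {
    if (!inherits(p, "kinematic_pulse"))
      stop("sim_config: boundary_kinematics entries must be kinematic_pulse objects")
  }
  # the latent-field mixing below needs |rho_eff| <= 1 after camera noise
  infl <- (cfg$band_amplitude^2 + cfg$noise_sd^2) / max(cfg$band_amplitude^2, .Machine$double.eps)
  rhos <- c(cfg$coloc_rho, vapply(cfg$coloc_patches, function(p) p$rho, numeric(1)))
  if (length(rhos) && any(abs(rhos) * infl > 1))
    stop("sim_config: coloc_rho unreachable: band_amplitude too small relative to noise_sd")
  invisible(cfg)
}

#' Planted boundary kinematic pulse
#'
#' Describes one protrusion or retraction: over frames
#' `start_frame..end_frame` the boundary moves at `speed_um_per_s` along its
#' outward normal inside an arclength window of extent `width_um` centered at
#' `center_arclength_um`; the window center may drift laterally by
#' `drift_sectors_per_frame` sectors per frame, which plants a traveling
#' wave of angle `atan(drift_sectors_per_frame)` in heatmap coordinates.
#'
#' @param kind "protrusion" or "retraction".
#' @param start_frame,end_frame frame indices (1-based), start < end.
#' @param center_arclength_um window center on the resting boundary.
#' @param width_um window extent along the boundary (> 0).
#' @param speed_um_per_s unsigned normal speed; the sign is set by `kind`.
#' @param drift_sectors_per_frame lateral drift of the window center.
#' @return object of class `kinematic_pulse`.
#' @export
kinematic_pulse <- function(kind = c("protrusion", "retraction"),
                            start_frame, end_frame,
                            center_arclength_um, width_um,
                            speed_um_per_s,
                            drift_sectors_per_frame = 0) {
  kind <- match.arg(kind)
  if (start_frame >= end_frame)
    stop("kinematic_pulse: start_frame must be < end_frame")
  if (width_um <= 0) stop("kinematic_pulse: width_um must be > 0")
  if (speed_um_per_s < 0) stop("kinematic_pulse: speed_um_per_s must be >= 0")
  structure(list(kind = kind, start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 center_arclength_um = center_arclength_um,
                 width_um = width_um, speed_um_per_s = speed_um_per_s,
                 drift_sectors_per_frame = drift_sectors_per_frame),
            class = "kinematic_pulse")
}

#' Planted adhesion site
#'
#' @param center_um c(x, y) offset of the ellipse center from the cell
#'   center, um.
#' @param semi_axes_um c(a, b) ellipse semi-axes, um.
#' @param angle_deg orientation of the a-axis from the x-axis.
#' @param intensity added intensity of the punctum.
#' @return object of class `adhesion_site_spec`.
#' @export
adhesion_site_spec <- function(center_um, semi_axes_um, angle_deg = 0,
                               intensity = 150) {
  stopifnot(length(center_um) == 2L, length(semi_axes_um) == 2L,
            all(semi_axes_um > 0))
  structure(list(center_um = as.numeric(center_um),
                 semi_axes_um = as.numeric(semi_axes_um),
                 angle_deg = angle_deg, intensity = intensity),
            class = "adhesion_site_spec")
}

# Evaluate a seeded expression without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
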