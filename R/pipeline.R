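# End-to-end analysis driver: segmentation -> boundaries -> sectors ->
# velocity heatmap -> edge band -> colocalization heatmap -> coupling ->
# events -> summaries, plus on-disk output with a provenance manifest.

#' Pipeline configuration
#'
#' @param pixel_size_um,frame_interval_s calibration (required, > 0).
#' @param sector_length_um boundary sector length (default 10).
#' @param band_depth_um edge-band depth (default 2).
#' @param value_threshold binarization threshold for velocity events.
#' @param coloc_event_threshold threshold for colocalization events.
#' @param min_event_area minimum event area, heatmap cells.
#' @param adhesion_min_area_um2 adhesion size-exclusion threshold.
#' @param search_um sector-tracking normal search half-window.
#' @param seed integer seed for any stochastic stage.
#' @param simulate optional list of [sim_config()] overrides; when present
#'   the pipeline generates its input movie instead of reading one.
#' @param input_ch1,input_ch2 TIFF paths of the two channels (when not
#'   simulating).
#' @param out_dir output directory.
#' @param render whether to render heatmap PNGs (requires a working png
#'   device; CSV output is unaffected).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um, frame_interval_s,
                            sector_length_um = 10, band_depth_um = 2,
                            value_threshold = 0.3,
                            coloc_event_threshold = 0.5,
                            min_event_area = 6L,
                            adhesion_min_area_um2 = 0.1,
                            search_um = 5, seed = 1L,
                            simulate = NULL,
                            input_ch1 = NULL, input_ch2 = NULL,
                            out_dir = "edgedyn_out", render = FALSE) {
  cfg <- list(pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              sector_length_um = sector_length_um,
              band_depth_um = band_depth_um,
              value_threshold = value_threshold,
              coloc_event_threshold = coloc_event_threshold,
              min_event_area = as.integer(min_event_area),
              adhesion_min_area_um2 = adhesion_min_area_um2,
              search_um = search_um, seed = as.integer(seed),
              simulate = simulate, input_ch1 = input_ch1,
              input_ch2 = input_ch2, out_dir = out_dir, render = render)
  for (f in c("pixel_size_um", "frame_interval_s", "sector_length_um",
              "band_depth_um", "search_um")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("pipeline_config: field '", f, "' must be a positive number")
  }
  if (cfg$min_event_area < 1L)
    stop("pipeline_config: field 'min_event_area' must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Analyze a two-channel movie in memory
#'
#' Runs segmentation, boundary extraction, sectorization (sector count fixed
#' by the first frame so heatmap rows align), sector tracking, velocity and
#' colocalization heatmaps, coupling, and event extraction.
#'
#' @param movie an `edge_movie`.
#' @param config a `pipeline_config`.
#' @return list: masks, boundaries, displacements, velocity_hm, coloc_hm,
#'   coupling (normalized as a single-cell set), velocity_events,
#'   coloc_events, velocity_summary, coloc_summary, n_sectors, n_frames.
#' @export
analyze_movie <- function(movie, config) {
  stopifnot(inherits(movie, "edge_movie"), inherits(config, "pipeline_config"))
  n_frames <- dim(movie$ch1)[3]
  masks <- segment_movie(movie)
  boundaries <- lapply(masks, extract_boundary)
  b1 <- discretize_sectors(boundaries[[1]], config$sector_length_um)
  n_sec <- attr(b1, "n_sectors")
  boundaries <- lapply(boundaries, discretize_sectors,
                       sector_length_um = config$sector_length_um,
                       n_sectors = n_sec)
  message(sprintf("[edgedyn] %d frames, %d sectors (perimeter %.1f um)",
                  n_frames, n_sec, boundaries[[1]]$perimeter_um))
  displacements <- lapply(seq_len(n_frames - 1L), function(f)
    track_sectors(boundaries[[f]], boundaries[[f + 1L]],
                  search_um = config$search_um))
  vhm <- build_velocity_heatmap(displacements, movie$frame_interval_s)
  bands <- lapply(seq_len(n_frames), function(f)
    make_edge_band(masks[[f]], boundaries[[f]], config$band_depth_um))
  chm <- build_coloc_heatmap(movie, masks, bands)
  # align: coloc column t pairs with the velocity column for frames t -> t+1
  chm_aligned <- new_edge_heatmap(chm$raw[, -n_frames, drop = FALSE],
                                  chm$norm[, -n_frames, drop = FALSE],
                                  chm$missing[, -n_frames, drop = FALSE],
                                  chm$frame_interval_s, "colocalization")
  cpl <- normalize_across_cells(coupling_map(vhm, chm_aligned))[[1]]
  vev <- extract_events(vhm, config$value_threshold, config$min_event_area)
  cev <- extract_events(chm, config$coloc_event_threshold,
                        config$min_event_area)
  dur <- n_frames * movie$frame_interval_s
  message(sprintf("[edgedyn] %d membrane events, %d colocalization events",
                  nrow(vev), nrow(cev)))
  list(masks = masks, boundaries = boundaries, displacements = displacements,
       velocity_hm = vhm, coloc_hm = chm, coupling = cpl,
       velocity_events = vev, coloc_events = cev,
       velocity_summary = summarize_events(vev, dur),
       coloc_summary = summarize_events(cev, dur),
       n_sectors = n_sec, n_frames = n_frames)
}

#' Run the full pipeline and write the result bundle to disk
#'
#' Generates (or reads) the movie, analyzes it, and writes masks,
#' boundaries, the three heatmaps, event tables, summaries, and a
#' machine-readable manifest carrying the config hash.
#'
#' @param config a `pipeline_config`.
#' @return invisible list: the `analyze_movie()` bundle plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$pixel_size_um <- config$pixel_size_um
    sim_args$frame_interval_s <- config$frame_interval_s
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (!is.null(sim_args$pulses)) {
      sim_args$boundary_kinematics <-
        lapply(sim_args$pulses, function(p) do.call(kinematic_pulse, p))
      sim_args$pulses <- NULL
    }
    sim <- generate_cell_movie(do.call(sim_config, sim_args))
    movie <- sim$movie
    write_ground_truth(sim$truth, out)
    write_tiff(movie$ch1, file.path(out, "channel1.tif"))
    write_tiff(movie$ch2, file.path(out, "channel2.tif"))
  } else {
    if (is.null(config$input_ch1) || is.null(config$input_ch2))
      stop("run_pipeline: input_ch1/input_ch2 required when not simulating")
    for (p in c(config$input_ch1, config$input_ch2))
      if (!file.exists(p)) stop("run_pipeline: input not found: ", p)
    movie <- structure(list(ch1 = read_tiff(config$input_ch1),
                            ch2 = read_tiff(config$input_ch2),
                            pixel_size_um = config$pixel_size_um,
                            frame_interval_s = config$frame_interval_s,
                            channel_names = c("ch1", "ch2")),
                       class = "edge_movie")
  }
  res <- analyze_movie(movie, config)

  # provenance hash covers the scientific parameters, not the I/O paths
  hash_fields <- setdiff(names(config),
                         c("out_dir", "input_ch1", "input_ch2", "render"))
  cfg_hash <- digest::digest(unclass(config)[hash_fields])
  files <- list(
    masks = "masks.tif", boundaries = "boundaries.csv",
    velocity_heatmap = "velocity_heatmap.csv",
    coloc_heatmap = "coloc_heatmap.csv",
    coupling_heatmap = "coupling_heatmap.csv",
    membrane_events = "membrane_events.csv",
    coloc_events = "coloc_events.csv",
    summaries = "summaries.json")
  mask_arr <- array(0, dim = c(dim(res$masks[[1]]$mask), res$n_frames))
  for (f in seq_len(res$n_frames)) mask_arr[, , f] <- res$masks[[f]]$mask * 1
  write_tiff(mask_arr, file.path(out, files$masks))
  write_boundaries_csv(res$boundaries, file.path(out, files$boundaries), cfg_hash)
  write_heatmap_csv(res$velocity_hm$norm, file.path(out, files$velocity_heatmap), cfg_hash)
  write_heatmap_csv(res$coloc_hm$norm, file.path(out, files$coloc_heatmap), cfg_hash)
  write_heatmap_csv(res$coupling$norm, file.path(out, files$coupling_heatmap), cfg_hash)
  write_events_csv(res$velocity_events, file.path(out, files$membrane_events), cfg_hash)
  write_events_csv(res$coloc_events, file.path(out, files$coloc_events), cfg_hash)
  summaries <- list(config_hash = cfg_hash,
                    membrane = res$velocity_summary,
                    colocalization = res$coloc_summary,
                    coupling_mean_raw = res$coupling$mean_raw)
  jsonlite::write_json(summaries, file.path(out, files$summaries),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (isTRUE(config$render)) {
    render_heatmap(res$velocity_hm, file.path(out, "velocity_heatmap.png"))
    render_heatmap(res$coloc_hm, file.path(out, "coloc_heatmap.png"))
    render_coupling(res$coupling, file.path(out, "coupling_heatmap.png"))
  }
  manifest <- list(package = "edgedyn",
                   version = as.character(packageVersion("edgedyn")),
                   config_hash = cfg_hash, seed = config$seed,
                   n_sectors = res$n_sectors, n_frames = res$n_frames,
                   n_membrane_events = nrow(res$velocity_events),
                   n_coloc_events = nrow(res$coloc_events),
                   outputs = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

write_ground_truth <- function(truth, out_dir) {
  write.csv(truth$events, file.path(out_dir, "truth_events.csv"),
            row.names = FALSE)
  sv <- as.data.frame(truth$sector_velocity_um_per_s)
  names(sv) <- paste0("frame_pair_", seq_len(ncol(sv)))
  write.csv(cbind(sector = seq_len(nrow(sv)), sv),
            file.path(out_dir, "truth_sector_velocity_um_per_s.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

write_heatmap_csv <- function(m, path, cfg_hash = NULL) {
  df <- as.data.frame(m)
  names(df) <- paste0("frame_", seq_len(ncol(df)))
  df <- cbind(sector = seq_len(nrow(df)), df)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg_hash)) writeLines(paste0("# config_hash: ", cfg_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a heatmap CSV written by the pipeline back into a matrix
#' @param path CSV path.
#' @return numeric matrix (sectors x frames).
#' @export
read_heatmap_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  as.matrix(df[, -1, drop = FALSE])
}

write_boundaries_csv <- function(boundaries, path, cfg_hash = NULL) {
  rows <- lapply(seq_along(boundaries), function(f) {
    b <- boundaries[[f]]
    data.frame(frame = f, vertex = seq_len(nrow(b$xy)),
               x_um = b$xy[, 1], y_um = b$xy[, 2],
               sector_id = b$sector_id)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg_hash)) writeLines(paste0("# config_hash: ", cfg_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

write_events_csv <- function(events, path, cfg_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg_hash)) writeLines(paste0("# config_hash: ", cfg_hash), con)
  write.csv(as.data.frame(events), con, row.names = FALSE)
  invisible(path)
}

# heatmap rendering with the conventional encodings: velocity blue (-1) ->
# green (0) -> red (+1); colocalization blue (0) -> red (1); coupling
# blue/cyan/green/orange/red over [-1, 1]. Rendering failure (no png
# device) degrades to a warning; CSV outputs are authoritative.
render_heatmap <- function(hm, path) {
  ok <- tryCatch({
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices.dev_off_safe(), add = TRUE)
    if (hm$flavor == "velocity") {
      pal <- grDevices::colorRampPalette(c("blue", "green", "red"))(101)
      z <- (t(hm$norm) + 1) / 2
    } else {
      pal <- grDevices::colorRampPalette(c("blue", "red"))(101)
      z <- t(hm$norm)
    }
    z[is.na(z)] <- 0
    graphics::image(z, col = pal, zlim = c(0, 1),
                    xlab = "time (frames)", ylab = "sector",
                    main = hm$flavor)
    TRUE
  }, error = function(e) {
    warning("render_heatmap: ", conditionMessage(e))
    FALSE
  })
  invisible(ok)
}

render_coupling <- function(cpl, path) {
  ok <- tryCatch({
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices.dev_off_safe(), add = TRUE)
    pal <- grDevices::colorRampPalette(
      c("blue", "cyan", "green", "orange", "red"))(101)
    z <- (t(cpl$norm) + 1) / 2
    z[is.na(z)] <- 0.5
    graphics::image(z, col = pal, zlim = c(0, 1),
                    xlab = "time (frames)", ylab = "sector",
                    main = "velocity-colocalization coupling")
    TRUE
  }, error = function(e) {
    warning("render_coupling: ", conditionMessage(e))
    FALSE
  })
  invisible(ok)
}

grDevices.dev_off_safe <- function() {
  if (grDevices::dev.cur() > 1) grDevices::dev.off()
}
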