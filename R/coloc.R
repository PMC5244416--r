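# Edge-band colocalization: a 2 um-deep band just inside the cell boundary is
# partitioned into the boundary sectors, and within each band region the
# colocalization coefficient is the Pearson-type correlation of
# background-subtracted green and red pixel intensities,
#   coloc = Cov(G - muG, R - muR) / sqrt(Var(G - muG) * Var(R - muR)).
# Backgrounds are the mean intensities outside a 2 um dilation of the cell
# mask (the source analysis does not define its background region; this
# choice is configurable and, being a per-frame constant, does not alter the
# correlation itself).

#' Build the 2 um edge band and assign band pixels to boundary sectors
#'
#' The band is the set of in-mask pixels within `depth_um` of the background
#' (sub-pixel erosion via the exact Euclidean distance transform rather than
#' an integer structuring element, for calibration independence). Each band
#' pixel inherits the sector id of the nearest boundary vertex.
#'
#' @param mask a `cell_mask`.
#' @param boundary the matching sectorized `cell_boundary`.
#' @param depth_um band depth (default 2).
#' @return object of class `edge_band`: list(band = logical matrix,
#'   region_id = integer matrix (0 outside the band), n_regions, depth_um).
#' @export
make_edge_band <- function(mask, boundary, depth_um = 2) {
  stopifnot(inherits(mask, "cell_mask"), inherits(boundary, "cell_boundary"))
  n_sec <- attr(boundary, "n_sectors")
  if (is.null(n_sec)) stop("make_edge_band: boundary is not sectorized")
  px <- mask$pixel_size_um
  if (depth_um < 2 * px)
    stop("make_edge_band: depth_um must be at least 2 pixels at this calibration")
  d_out <- distance_to(!mask$mask) * px   # distance to nearest background px
  band <- mask$mask & d_out <= depth_um
  if (!any(mask$mask & !band))
    stop("make_edge_band: erosion empties the mask (cell thinner than 2x depth)")
  region <- matrix(0L, nrow(band), ncol(band))
  w <- which(band, arr.ind = TRUE)
  bx <- (w[, 2] - 1) * px; by <- (w[, 1] - 1) * px
  vx <- boundary$xy[, 1]; vy <- boundary$xy[, 2]
  # nearest boundary vertex per band pixel, chunked to bound memory
  sec <- integer(nrow(w))
  chunk <- 4096L
  for (i0 in seq(1L, nrow(w), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(w))
    dd <- outer(bx[i0:i1], vx, "-")^2 + outer(by[i0:i1], vy, "-")^2
    sec[i0:i1] <- boundary$sector_id[max.col(-dd, ties.method = "first")]
  }
  region[w] <- sec
  structure(list(band = band, region_id = region, n_regions = n_sec,
                 depth_um = depth_um),
            class = "edge_band")
}

#' Colocalization coefficient of one band region
#'
#' Pearson-type correlation of paired, background-subtracted pixel values.
#' The background constants shift the means only, so the value equals the
#' Pearson correlation of (G, R); both are computed from the covariance /
#' variance definition.
#'
#' @param G,R paired pixel intensity vectors for one region.
#' @param bg_G,bg_R per-channel background levels to subtract.
#' @param min_pixels minimum region pixel count.
#' @return correlation in \[-1, 1\], or NA (flagged undefined) when either
#'   channel has zero variance or the region is too small.
#' @export
region_coloc <- function(G, R, bg_G = 0, bg_R = 0, min_pixels = 10L) {
  stopifnot(length(G) == length(R))
  if (length(G) < min_pixels) return(NA_real_)
  g <- G - bg_G
  r <- R - bg_R
  g <- g - mean(g)
  r <- r - mean(r)
  vg <- sum(g * g)
  vr <- sum(r * r)
  if (vg <= 0 || vr <= 0) return(NA_real_)
  sum(g * r) / sqrt(vg * vr)
}

#' Estimate per-channel background outside the dilated cell mask
#'
#' @param frame intensity matrix.
#' @param mask `cell_mask` for the same frame.
#' @param margin_um dilation margin (default 2).
#' @return mean background intensity (scalar).
#' @export
estimate_background <- function(frame, mask, margin_um = 2) {
  px <- mask$pixel_size_um
  d <- distance_to(mask$mask) * px
  bg <- d > margin_um
  if (!any(bg)) return(mean(frame[!mask$mask]))
  mean(frame[bg])
}

#' Build the colocalization heatmap of a movie
#'
#' One column per frame, one row per band region (= boundary sector). Raw
#' values are signed correlations; the display normalization clips negatives
#' to 0 so the rendered scale runs 0 (no colocalization) to 1 (perfect).
#'
#' @param movie an `edge_movie` (channels `ch1` = green/marker, `ch2` =
#'   red/actin).
#' @param masks list of `cell_mask` per frame.
#' @param bands list of `edge_band` per frame.
#' @param min_pixels minimum pixels per region.
#' @return an `edge_heatmap` with `flavor = "colocalization"`; `raw` holds
#'   signed values, `norm` the clipped display scale, undefined regions are
#'   masked.
#' @export
build_coloc_heatmap <- function(movie, masks, bands, min_pixels = 10L) {
  stopifnot(inherits(movie, "edge_movie"))
  if (!identical(dim(movie$ch1), dim(movie$ch2)))
    stop("build_coloc_heatmap: channel shape mismatch")
  n_frames <- dim(movie$ch1)[3]
  stopifnot(length(masks) == n_frames, length(bands) == n_frames)
  n_reg <- bands[[1]]$n_regions
  raw <- matrix(NA_real_, n_reg, n_frames)
  for (f in seq_len(n_frames)) {
    g_frame <- movie$ch1[, , f]
    r_frame <- movie$ch2[, , f]
    bg_g <- estimate_background(g_frame, masks[[f]])
    bg_r <- estimate_background(r_frame, masks[[f]])
    reg <- bands[[f]]$region_id
    for (s in seq_len(n_reg)) {
      sel <- reg == s
      raw[s, f] <- region_coloc(g_frame[sel], r_frame[sel],
                                bg_g, bg_r, min_pixels = min_pixels)
    }
  }
  miss <- is.na(raw)
  norm <- pmax(raw, 0)
  norm[miss] <- NA_real_
  new_edge_heatmap(raw, norm, miss, movie$frame_interval_s, "colocalization")
}

#' Summarize colocalization events
#'
#' Same contract as [summarize_events()]; provided as a named entry point for
#' colocalization heatmap events (default threshold 0.5 on the 0..1 display
#' scale).
#'
#' @inheritParams summarize_events
#' @export
coloc_event_summary <- function(events, movie_duration_s) {
  summarize_events(events, movie_duration_s)
}
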