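# Sector-velocity heatmaps and membrane event extraction.
#
# The heatmap convention follows the standard edge-kymograph layout: rows are
# boundary sectors (the closed edge, so row space wraps around), columns are
# frame pairs, values are the normal velocity V = d . n of each sector. The
# normalized map divides by the maximum |V| over the analysis set, so V = 1
# is the fastest protrusion, V = -1 the fastest retraction, V = 0 quiescence.

#' Build a velocity heatmap from tracked sector displacements
#'
#' @param displacements list of per-frame-pair data.frames from
#'   [track_sectors()] (length = n_frames - 1).
#' @param frame_interval_s seconds per frame.
#' @param norm_max optional normalization constant (um/frame); by default the
#'   maximum |V_raw| of this map. Pass the analysis-set maximum to normalize a
#'   cohort of cells on a common scale.
#' @return object of class `edge_heatmap` with fields `raw` (um/frame),
#'   `norm` (dimensionless, |.| <= 1), `missing` (logical matrix),
#'   `frame_interval_s`, `flavor = "velocity"`, `norm_max`.
#' @export
build_velocity_heatmap <- function(displacements, frame_interval_s,
                                   norm_max = NULL) {
  stopifnot(length(displacements) >= 1L)
  n_sec <- nrow(displacements[[1]])
  raw <- vapply(displacements, function(d) {
    stopifnot(nrow(d) == n_sec)
    v <- d$v_normal_um
    v[d$missing] <- NA_real_
    v
  }, numeric(n_sec))
  raw <- matrix(raw, nrow = n_sec)
  miss <- is.na(raw)
  if (any(colSums(!miss) == 0L))
    stop("build_velocity_heatmap: a frame column has no tracked sectors")
  if (is.null(norm_max)) norm_max <- max(abs(raw), na.rm = TRUE)
  norm <- if (norm_max > 0) raw / norm_max else raw
  structure(list(raw = raw, norm = norm, missing = miss,
                 frame_interval_s = frame_interval_s,
                 flavor = "velocity", norm_max = norm_max),
            class = "edge_heatmap")
}

# shared constructor used by the colocalization module
new_edge_heatmap <- function(raw, norm, missing, frame_interval_s, flavor,
                             norm_max = NA_real_) {
  structure(list(raw = raw, norm = norm, missing = missing,
                 frame_interval_s = frame_interval_s, flavor = flavor,
                 norm_max = norm_max),
            class = "edge_heatmap")
}

#' @export
print.edge_heatmap <- function(x, ...) {
  cat(sprintf("<edge_heatmap [%s]> %d sectors x %d frames, %.3g s/frame\n",
              x$flavor, nrow(x$raw), ncol(x$raw), x$frame_interval_s))
  invisible(x)
}

#' Extract membrane (or colocalization) events from a heatmap
#'
#' Cells with |normalized value| >= `value_threshold` are binarized
#' (separately per sign for velocity maps; positive side only for
#' colocalization maps, whose display scale runs 0..1), labeled with
#' 8-connected components including circular wraparound in the sector
#' dimension, and components smaller than `min_area` heatmap cells are
#' dropped. Each component's duration, area and major-axis angle (from the
#' time axis, via second central moments, folded to \[0, 90\] degrees) are
#' reported; events with angle strictly greater than 10 degrees are traveling
#' waves.
#'
#' @param hm an `edge_heatmap`.
#' @param value_threshold binarization threshold on the normalized map.
#' @param min_area minimum component area (heatmap cells).
#' @param wave_angle_deg traveling-wave angle threshold (strict inequality).
#' @return data.frame of events: event_id, polarity, area_cells,
#'   sector_min/max, frame_min/max, duration_s, angle_deg,
#'   is_traveling_wave; plus a `cells` list-column of (sector, frame)
#'   member matrices.
#' @export
extract_events <- function(hm, value_threshold = 0.3, min_area = 6L,
                           wave_angle_deg = 10) {
  stopifnot(inherits(hm, "edge_heatmap"))
  v <- hm$norm
  if (any(!is.finite(v) & !hm$missing))
    stop("extract_events: non-finite heatmap values outside the missing mask")
  v[hm$missing] <- 0
  sides <- if (hm$flavor == "velocity") {
    list(protrusion = v >= value_threshold, retraction = v <= -value_threshold)
  } else {
    list(colocalization = v >= value_threshold)
  }
  rows <- list()
  for (pol in names(sides)) {
    lab <- label_wrapped(sides[[pol]])
    for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
      w <- which(lab == id, arr.ind = TRUE)   # col1 = sector, col2 = frame
      if (nrow(w) < min_area) next
      ang <- component_angle(w[, 1], w[, 2], nrow(v))
      rows[[length(rows) + 1L]] <- data.frame(
        polarity = pol, area_cells = nrow(w),
        sector_min = min(w[, 1]), sector_max = max(w[, 1]),
        frame_min = min(w[, 2]), frame_max = max(w[, 2]),
        duration_s = (max(w[, 2]) - min(w[, 2]) + 1L) * hm$frame_interval_s,
        angle_deg = ang, is_traveling_wave = ang > wave_angle_deg,
        stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "cells") <- w
    }
  }
  if (!length(rows)) {
    ev <- data.frame(event_id = integer(), polarity = character(),
                     area_cells = integer(), sector_min = integer(),
                     sector_max = integer(), frame_min = integer(),
                     frame_max = integer(), duration_s = numeric(),
                     angle_deg = numeric(), is_traveling_wave = logical())
    attr(ev, "cells") <- list()
    return(ev)
  }
  cells <- lapply(rows, attr, "cells")
  ev <- do.call(rbind, rows)
  ev <- cbind(event_id = seq_len(nrow(ev)), ev)
  attr(ev, "cells") <- cells
  ev
}

# 8-connected labeling with circular wraparound along rows (sectors)
label_wrapped <- function(mask) {
  lab <- label_components(mask, 8L)
  n <- nrow(mask)
  if (n < 2L) return(lab)
  # merge labels adjacent across the row 1 / row n seam (8-connectivity)
  nc <- ncol(mask)
  pairs <- list()
  for (j in seq_len(nc)) {
    if (lab[1, j] > 0L) {
      for (jj in intersect(c(j - 1L, j, j + 1L), seq_len(nc))) {
        if (lab[n, jj] > 0L)
          pairs[[length(pairs) + 1L]] <- c(lab[1, j], lab[n, jj])
      }
    }
  }
  if (!length(pairs)) return(lab)
  k <- max(lab)
  parent <- seq_len(k)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (pr in pairs) {
    ra <- findp(pr[1]); rb <- findp(pr[2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  remap <- vapply(seq_len(k), findp, integer(1))
  dense <- match(remap, sort(unique(remap)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

# major-axis orientation of a heatmap component, measured from the time
# (frame) axis, folded to [0, 90] degrees. Sector coordinates are unwrapped
# first when the component crosses the circular seam.
component_angle <- function(sectors, frames, n_sectors) {
  present <- sort(unique(sectors))
  if (1L %in% present && n_sectors %in% present &&
      length(present) < n_sectors) {
    # rotate so the occupied rows are contiguous: find a gap
    gap <- setdiff(seq_len(n_sectors), present)[1]
    sectors <- ((sectors - gap) %% n_sectors)
  }
  x <- frames; y <- sectors
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  abs(theta)   # atan2 range gives theta in (-90, 90]; fold to [0, 90]
}

#' Summarize membrane events for one cell
#'
#' @param events data.frame from [extract_events()].
#' @param movie_duration_s total movie duration in seconds.
#' @param wave_angle_deg traveling-wave threshold (strict).
#' @return list: n_events, events_per_minute, mean_duration_s,
#'   mean_angle_deg, percent_traveling_waves. With zero events the rate is 0
#'   and the means are NA (flagged undefined, not zero).
#' @export
summarize_events <- function(events, movie_duration_s, wave_angle_deg = 10) {
  n <- nrow(events)
  if (n == 0L) {
    return(list(n_events = 0L, events_per_minute = 0,
                mean_duration_s = NA_real_, mean_angle_deg = NA_real_,
                percent_traveling_waves = NA_real_))
  }
  list(n_events = n,
       events_per_minute = n / (movie_duration_s / 60),
       mean_duration_s = mean(events$duration_s),
       mean_angle_deg = mean(events$angle_deg),
       percent_traveling_waves = 100 * mean(events$angle_deg > wave_angle_deg))
}
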