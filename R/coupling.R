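# Velocity-colocalization coupling: the elementwise product of the
# normalized velocity map (in [-1, 1]) and the display-normalized
# colocalization map (in [0, 1]). Interpretation anchors follow the standard
# five-level legend: C = 1 coupled protrusion/high colocalization, C = 0.5
# protrusion/low colocalization, C = 0 quiescence, C = -0.5 retraction/low
# colocalization, C = -1 coupled retraction/high colocalization.

#' Couple a velocity heatmap with a colocalization heatmap
#'
#' @param v an `edge_heatmap` with flavor "velocity".
#' @param coloc an `edge_heatmap` with flavor "colocalization", same shape
#'   and frame alignment as `v`.
#' @return object of class `coupling_map`: list(raw = elementwise product,
#'   norm = NULL until [normalize_across_cells()], missing, frame_interval_s,
#'   mean_raw = scalar per-cell summary mean of the raw map).
#' @export
coupling_map <- function(v, coloc) {
  stopifnot(inherits(v, "edge_heatmap"), inherits(coloc, "edge_heatmap"))
  if (v$flavor != "velocity" || coloc$flavor != "colocalization")
    stop("coupling_map: expects one velocity and one colocalization heatmap")
  if (!identical(dim(v$norm), dim(coloc$norm)))
    stop("coupling_map: heatmap shapes differ (",
         paste(dim(v$norm), collapse = "x"), " vs ",
         paste(dim(coloc$norm), collapse = "x"), ")")
  miss <- v$missing | coloc$missing
  raw <- v$norm * coloc$norm
  raw[miss] <- NA_real_
  structure(list(raw = raw, norm = NULL, missing = miss,
                 frame_interval_s = v$frame_interval_s,
                 mean_raw = mean(raw, na.rm = TRUE)),
            class = "coupling_map")
}

#' Normalize coupling maps across an analysis set of cells
#'
#' All maps are divided by the same symmetric scale
#' `s = max(|set max|, |set min|)`, mapping the extreme raw coupling in the
#' set to +/-1 while preserving zero (so quiescence keeps its C = 0
#' meaning) and the sign of every entry.
#'
#' @param maps list of `coupling_map` objects (>= 1).
#' @return the same list with `norm` filled and attribute `scale` = s. An
#'   all-zero set is returned unchanged with a warning.
#' @export
normalize_across_cells <- function(maps) {
  if (inherits(maps, "coupling_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "coupling_map")))
  s <- max(vapply(maps, function(m) {
    if (all(is.na(m$raw))) 0 else max(abs(m$raw), na.rm = TRUE)
  }, numeric(1)))
  if (s == 0) {
    warning("normalize_across_cells: all coupling values are zero; maps unchanged")
    for (i in seq_along(maps)) maps[[i]]$norm <- maps[[i]]$raw
  } else {
    for (i in seq_along(maps)) maps[[i]]$norm <- maps[[i]]$raw / s
  }
  attr(maps, "scale") <- s
  maps
}

#' Five-level interpretation legend for coupling maps
#'
#' @return data.frame of anchor values, meanings and display colors.
#' @export
coupling_legend <- function() {
  data.frame(
    anchor = c(1, 0.5, 0, -0.5, -1),
    meaning = c("coupled protrusion, high colocalization",
                "protrusion, low colocalization",
                "quiescence / low colocalization",
                "retraction, low colocalization",
                "coupled retraction, high colocalization"),
    color = c("red", "orange", "green", "cyan", "blue"),
    stringsAsFactors = FALSE)
}
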