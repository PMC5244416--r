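# Cell segmentation. The graph-cut segmenter used by the original analysis
# platform is out of scope; for the high-contrast movies this package targets
# (and generates) a global between-class-variance threshold followed by hole
# filling and largest-component selection is adequate and is documented as a
# pluggable substitution.

#' Segment a single cell from an intensity frame
#'
#' Global Otsu threshold, hole fill, largest connected component. The frame is
#' expected to contain exactly one cell; a second component larger than
#' `max_secondary_frac` of the largest is treated as a segmentation failure.
#'
#' @param frame numeric intensity matrix (typically the actin channel).
#' @param pixel_size_um pixel pitch, um.
#' @param threshold optional fixed threshold; default Otsu.
#' @param max_secondary_frac largest allowed secondary-component area,
#'   relative to the main component.
#' @param frame_id integer used in error messages.
#' @return object of class `cell_mask`: list(mask = logical matrix,
#'   pixel_size_um, threshold).
#' @export
segment_cell <- function(frame, pixel_size_um, threshold = NULL,
                         max_secondary_frac = 0.25, frame_id = NA_integer_) {
  stopifnot(is.matrix(frame), pixel_size_um > 0)
  thr <- if (is.null(threshold)) otsu_threshold(frame) else threshold
  fg <- frame > thr
  if (!any(fg))
    stop("segment_cell: no cell found",
         if (!is.na(frame_id)) paste0(" in frame ", frame_id) else "")
  fg <- fill_holes(fg)
  lab <- label_components(fg, 8L)
  sizes <- tabulate(lab[lab > 0L])
  main <- which.max(sizes)
  if (length(sizes) > 1L) {
    second <- max(sizes[-main])
    if (second > max_secondary_frac * sizes[main])
      stop("segment_cell: multiple large components",
           if (!is.na(frame_id)) paste0(" in frame ", frame_id) else "",
           " (", sizes[main], " and ", second, " px)")
  }
  structure(list(mask = lab == main, pixel_size_um = pixel_size_um,
                 threshold = thr),
            class = "cell_mask")
}

#' Segment every frame of a movie
#'
#' @param movie an `edge_movie` (see [generate_cell_movie()]) or a numeric
#'   array rows x cols x frames.
#' @param channel which channel to segment when `movie` is an `edge_movie`;
#'   defaults to the actin channel ("ch2").
#' @param ... passed to [segment_cell()].
#' @param pixel_size_um required when `movie` is a bare array.
#' @return list of `cell_mask`, one per frame.
#' @export
segment_movie <- function(movie, channel = "ch2", pixel_size_um = NULL, ...) {
  if (inherits(movie, "edge_movie")) {
    arr <- movie[[channel]]
    px <- movie$pixel_size_um
  } else {
    arr <- movie
    px <- pixel_size_um
    if (is.null(px)) stop("segment_movie: pixel_size_um required for arrays")
  }
  lapply(seq_len(dim(arr)[3]), function(f)
    segment_cell(arr[, , f], px, frame_id = f, ...))
}
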