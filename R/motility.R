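# Trajectory, wound-closure and subcellular-localization metrics.

#' Meandering index of a cell track
#'
#' Net start-to-end displacement divided by the summed step lengths
#' (displacement/distance), in \[0, 1\]. Tracks with missing frames are
#' used as given (linear interpolation over a gap would add collinear points
#' and leave the path length unchanged); a `has_gaps` flag is attached.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` (>= 2 rows).
#' @return scalar in \[0, 1\], NA (flagged) when the path length is zero.
#'   Attributes: `displacement_um`, `path_length_um`, `has_gaps`.
#' @export
meandering_index <- function(track) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("meandering_index: track needs >= 2 positions")
  if (any(!is.finite(track$x_um)) || any(!is.finite(track$y_um)))
    stop("meandering_index: non-finite coordinates")
  track <- track[order(track$frame), ]
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  path <- sum(sqrt(dx^2 + dy^2))
  disp <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
               (track$y_um[nrow(track)] - track$y_um[1])^2)
  mi <- if (path > 0) disp / path else NA_real_
  structure(mi, displacement_um = disp, path_length_um = path,
            has_gaps = any(diff(track$frame) > 1))
}

#' Percent wound area closed over time
#'
#' @param series data.frame with columns `t_h` (hours, must include 0) and
#'   `area_um2` (>= 0); `area_um2[t_h == 0]` must be > 0.
#' @return data.frame `t_h`, `area_um2`, `percent_closed` where
#'   percent_closed(t) = 100 (A0 - A(t)) / A0, clipped below at 0.
#' @export
wound_closure <- function(series) {
  stopifnot(all(c("t_h", "area_um2") %in% names(series)))
  if (!any(series$t_h == 0))
    stop("wound_closure: series must include the t = 0 timepoint")
  if (any(series$area_um2 < 0))
    stop("wound_closure: negative wound areas")
  a0 <- series$area_um2[series$t_h == 0][1]
  if (a0 <= 0) stop("wound_closure: initial wound area must be > 0")
  series <- series[order(series$t_h), ]
  series$percent_closed <- pmax(0, 100 * (a0 - series$area_um2) / a0)
  series
}

#' Cytoplasmic:nuclear mean intensity ratio
#'
#' @param frame intensity matrix.
#' @param nucleus_mask,cytoplasm_mask disjoint, non-empty logical matrices
#'   (cytoplasm = cell minus nucleus).
#' @return mean(cytoplasm) / mean(nucleus); NA (flagged undefined) when the
#'   nuclear mean is zero.
#' @export
cn_ratio <- function(frame, nucleus_mask, cytoplasm_mask) {
  stopifnot(is.matrix(frame),
            identical(dim(frame), dim(nucleus_mask)),
            identical(dim(frame), dim(cytoplasm_mask)))
  if (!any(nucleus_mask) || !any(cytoplasm_mask))
    stop("cn_ratio: both compartment masks must be non-empty")
  if (any(nucleus_mask & cytoplasm_mask))
    stop("cn_ratio: compartment masks overlap")
  mu_n <- mean(frame[nucleus_mask])
  if (mu_n == 0) return(NA_real_)
  mean(frame[cytoplasm_mask]) / mu_n
}
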