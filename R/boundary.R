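# Boundary extraction, sector discretization and frame-to-frame sector
# correspondence. A boundary frame is a closed, simple, counter-clockwise
# polyline in um with outward unit normals, uniform arclength spacing, and
# (after discretize_sectors) a sector id per vertex.

#' Extract a sub-pixel cell boundary from a mask
#'
#' The binary mask is lightly Gaussian-smoothed and the 0.5 level set traced
#' with marching squares (`grDevices::contourLines`), giving a sub-pixel
#' closed contour. The contour is oriented counter-clockwise, resampled to
#' uniform arclength spacing, and circularly smoothed to suppress pixel
#' staircase artifacts before outward normals are computed by central
#' differences.
#'
#' @param mask a `cell_mask` from [segment_cell()], or a logical matrix (then
#'   `pixel_size_um` must be given).
#' @param pixel_size_um pixel pitch when `mask` is a bare matrix.
#' @param smooth_sigma_px Gaussian sigma (pixels) for pre-contour mask
#'   smoothing.
#' @param vertex_spacing_px target arclength spacing of vertices, in pixels.
#' @return object of class `cell_boundary`: list with `xy` (n x 2 matrix,
#'   um, open ring, CCW), `normal` (n x 2 outward unit normals), `arclength`
#'   (n, um, from vertex 1), `perimeter_um`, `centroid_um`, `pixel_size_um`,
#'   and `sector_id` (NA until [discretize_sectors()]).
#' @export
extract_boundary <- function(mask, pixel_size_um = NULL,
                             smooth_sigma_px = 1, vertex_spacing_px = 1) {
  if (inherits(mask, "cell_mask")) {
    m <- mask$mask
    px <- mask$pixel_size_um
  } else {
    m <- mask
    px <- pixel_size_um
    if (is.null(px)) stop("extract_boundary: pixel_size_um required")
  }
  if (sum(bwperim_count(m)) < 16L)
    stop("extract_boundary: degenerate mask (< 16 boundary pixels)")
  z <- gaussian_blur(m * 1.0, smooth_sigma_px)
  # contourLines: x indexes rows of z, y indexes columns
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("extract_boundary: no 0.5 level set found")
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  # convert to physical coordinates: rows -> y, columns -> x, 0-based centers
  xy <- cbind(x = (cc$y - 1) * px, y = (cc$x - 1) * px)
  polygon_boundary(xy, pixel_size_um = px,
                   vertex_spacing_um = vertex_spacing_px * px,
                   smooth_sigma_vertices = 1.5)
}

#' Build a `cell_boundary` from a closed polygon
#'
#' Accepts any simple closed polygon (um coordinates), orients it
#' counter-clockwise, resamples to uniform arclength spacing, optionally
#' smooths the vertex chain circularly, and computes outward normals. Used
#' internally by [extract_boundary()] and directly when analytic boundary
#' coordinates are available (e.g. simulator ground truth).
#'
#' @param xy n x 2 matrix of vertices in um (open or closed ring).
#' @param pixel_size_um calibration carried along for downstream stages.
#' @param vertex_spacing_um target vertex spacing.
#' @param smooth_sigma_vertices circular Gaussian sigma in vertex units
#'   (0 = no smoothing).
#' @return a `cell_boundary` (see [extract_boundary()]).
#' @export
polygon_boundary <- function(xy, pixel_size_um = 1, vertex_spacing_um = 0.5,
                             smooth_sigma_vertices = 0) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  if (all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12)) xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 8L) stop("polygon_boundary: degenerate contour")
  # orient counter-clockwise (positive shoelace area)
  if (polygon_area(xy) < 0) xy <- xy[nrow(xy):1, , drop = FALSE]

  # resample to uniform arclength
  seg <- sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2))
  perim <- sum(seg)
  n_out <- max(64L, as.integer(round(perim / vertex_spacing_um)))
  s_in <- c(0, cumsum(seg))
  s_out <- seq(0, perim, length.out = n_out + 1L)[-(n_out + 1L)]
  ring <- rbind(xy, xy[1, ])
  rx <- stats::approx(s_in, ring[, 1], xout = s_out)$y
  ry <- stats::approx(s_in, ring[, 2], xout = s_out)$y

  sm <- circular_smooth(cbind(rx, ry), sigma = smooth_sigma_vertices)
  seg2 <- sqrt(rowSums((sm[c(2:n_out, 1), ] - sm)^2))
  perim2 <- sum(seg2)
  arclength <- c(0, cumsum(seg2))[seq_len(n_out)]

  # outward normals: rotate unit tangent by -90 deg; the +/-2-vertex central
  # difference suppresses residual pixel staircase in the tangent estimate.
  # For a CCW ring (t_x, t_y) -> (t_y, -t_x) points outward.
  sh <- function(o) sm[((seq_len(n_out) - 1 + o) %% n_out) + 1, , drop = FALSE]
  tang <- sh(2) - sh(-2)
  tlen <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(tlen, .Machine$double.eps)
  normal <- cbind(tang[, 2], -tang[, 1])
  centroid <- colMeans(sm)
  # sanity: ensure outward orientation by majority vote against the centroid
  if (mean(rowSums(normal * sweep(sm, 2, centroid))) < 0) normal <- -normal

  structure(list(xy = unname(sm), normal = unname(normal),
                 arclength = arclength, perimeter_um = perim2,
                 centroid_um = unname(centroid), pixel_size_um = pixel_size_um,
                 sector_id = rep(NA_integer_, n_out)),
            class = "cell_boundary")
}

# number of foreground pixels 4-adjacent to background (cheap perimeter proxy)
bwperim_count <- function(m) {
  mode(m) <- "logical"; m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(FALSE, m[-nr, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -nc, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

circular_smooth <- function(xy, sigma) {
  if (sigma <= 0) return(xy)
  n <- nrow(xy)
  h <- max(1L, min(ceiling(3 * sigma), (n - 1L) %/% 2L))
  k <- exp(-((-h:h)^2) / (2 * sigma^2)); k <- k / sum(k)
  out <- matrix(0, n, 2)
  for (o in -h:h) {
    idx <- ((seq_len(n) - 1 + o) %% n) + 1
    out <- out + k[o + h + 1] * xy[idx, , drop = FALSE]
  }
  out
}

#' Divide a boundary into contiguous equal-arclength sectors
#'
#' The number of sectors is `N = round(perimeter / sector_length_um)` (at
#' least 4), each of arclength perimeter/N. Sector 1 is anchored at the
#' boundary point where the ray from the cell centroid toward +x crosses the
#' boundary, which keeps heatmap rows comparable across frames.
#'
#' @param boundary a `cell_boundary`.
#' @param sector_length_um nominal sector length (default 10).
#' @param n_sectors optional fixed sector count overriding the rounding rule
#'   (used to keep N equal across frames of one movie).
#' @return the boundary with `sector_id` filled (integers 1..N) and
#'   attributes `n_sectors`, `sector_length_um`.
#' @export
discretize_sectors <- function(boundary, sector_length_um = 10,
                               n_sectors = NULL) {
  stopifnot(inherits(boundary, "cell_boundary"))
  P <- boundary$perimeter_um
  if (is.null(n_sectors)) {
    if (P < 2 * sector_length_um)
      stop("discretize_sectors: perimeter (", signif(P, 4),
           " um) shorter than two sectors")
    n_sectors <- max(4L, as.integer(round(P / sector_length_um)))
  }
  # anchor: vertex closest to the +x ray from the centroid
  rel <- sweep(boundary$xy, 2, boundary$centroid_um)
  ang <- atan2(rel[, 2], rel[, 1])
  anchor <- which.min(abs(ang))
  s0 <- boundary$arclength[anchor]
  s_rel <- (boundary$arclength - s0) %% P
  boundary$sector_id <- as.integer(floor(s_rel / (P / n_sectors))) %% n_sectors + 1L
  attr(boundary, "n_sectors") <- as.integer(n_sectors)
  attr(boundary, "sector_length_um") <- P / n_sectors
  boundary
}

# midpoint vertex index of each sector (vertex nearest the sector's
# mid-arclength, measured from the anchor)
sector_midpoints <- function(boundary) {
  n_sec <- attr(boundary, "n_sectors")
  if (is.null(n_sec)) stop("boundary is not sectorized")
  vapply(seq_len(n_sec), function(s) {
    idx <- which(boundary$sector_id == s)
    idx[ceiling(length(idx) / 2)]
  }, integer(1))
}

#' Track sector midpoints between two consecutive boundaries
#'
#' For each sector of `boundary_t`, a ray is cast from the sector midpoint
#' along the outward normal (both directions) and intersected with
#' `boundary_t1`; the signed distance delta of the nearest intersection gives
#' the displacement vector d = delta * n, so d . n = delta. If no
#' intersection lies within `search_um`, the nearest boundary point is used
#' as a fallback; sectors whose fallback displacement still exceeds
#' `search_um` are flagged missing (never silently zeroed).
#'
#' @param boundary_t,boundary_t1 sectorized `cell_boundary` objects with
#'   equal sector counts.
#' @param search_um normal-ray search half-window (default 5 um).
#' @return data.frame with one row per sector: sector, dx_um, dy_um, nx, ny,
#'   v_normal_um (= d . n), method ("ray"/"nearest"), missing (logical).
#' @export
track_sectors <- function(boundary_t, boundary_t1, search_um = 5) {
  n_sec <- attr(boundary_t, "n_sectors")
  if (is.null(n_sec) || is.null(attr(boundary_t1, "n_sectors")))
    stop("track_sectors: both boundaries must be sectorized")
  if (n_sec != attr(boundary_t1, "n_sectors"))
    stop("track_sectors: sector counts differ (", n_sec, " vs ",
         attr(boundary_t1, "n_sectors"), ")")
  mids <- sector_midpoints(boundary_t)
  B <- boundary_t1$xy
  a <- B
  b <- B[c(2:nrow(B), 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  out <- data.frame(sector = seq_len(n_sec), dx_um = NA_real_,
                    dy_um = NA_real_, nx = NA_real_, ny = NA_real_,
                    v_normal_um = NA_real_, method = NA_character_,
                    missing = FALSE)
  for (s in seq_len(n_sec)) {
    p <- boundary_t$xy[mids[s], ]
    n <- boundary_t$normal[mids[s], ]
    # solve p + delta*n = a + u*e for each edge
    den <- n[1] * ey - n[2] * ex          # cross(n, e) with sign
    ok <- abs(den) > 1e-12
    apx <- a[, 1] - p[1]; apy <- a[, 2] - p[2]
    delta <- (apx * ey - apy * ex) / den
    u <- (apx * n[2] - apy * n[1]) / (-den)
    hit <- ok & u >= 0 & u < 1 & abs(delta) <= search_um
    if (any(hit)) {
      dsel <- delta[hit][which.min(abs(delta[hit]))]
      out$dx_um[s] <- dsel * n[1]; out$dy_um[s] <- dsel * n[2]
      out$v_normal_um[s] <- dsel
      out$method[s] <- "ray"
    } else {
      dd <- sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2)
      j <- which.min(dd)
      d <- B[j, ] - p
      out$dx_um[s] <- d[1]; out$dy_um[s] <- d[2]
      out$v_normal_um[s] <- sum(d * n)
      out$method[s] <- "nearest"
      if (dd[j] > search_um) out$missing[s] <- TRUE
    }
    out$nx[s] <- n[1]; out$ny[s] <- n[2]
  }
  out
}
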