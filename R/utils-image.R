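# Low-level raster utilities shared by the segmentation, band and adhesion
# code. Images are numeric matrices indexed [row, col]; physical x runs along
# columns, physical y along rows, both in um with pixel centers at
# (col - 1) * pixel_size, (row - 1) * pixel_size.

#' Otsu's between-class-variance threshold
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("otsu_threshold: no finite intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  w1 <- w[n_bins] - w
  mu_tot <- m[n_bins]
  # between-class variance for threshold after bin k
  bcv <- ifelse(w > 0 & w1 > 0,
                (mu_tot * w - m * w[n_bins])^2 / (w * w1), 0)
  # the argmax can be a plateau (empty histogram gap between classes);
  # its midpoint keeps the threshold stable under small intensity rescaling
  k <- which(bcv >= max(bcv) * (1 - 1e-12))
  mids[round(mean(range(k)))]
}

#' Separable Gaussian blur with edge replication
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `img`.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_1d <- function(m, along_rows) {
    # pad by edge replication, accumulate shifted copies
    n <- if (along_rows) nrow(m) else ncol(m)
    idx_pad <- c(rep(1L, h), seq_len(n), rep(n, h))
    mp <- if (along_rows) m[idx_pad, , drop = FALSE] else m[, idx_pad, drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -h:h) {
      sel <- seq_len(n) + h + o
      out <- out + k[o + h + 1L] *
        (if (along_rows) mp[sel, , drop = FALSE] else mp[, sel, drop = FALSE])
    }
    out
  }
  conv_1d(conv_1d(img, TRUE), FALSE)
}

#' Label connected components of a binary matrix
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  cpp_label_components(mask, as.integer(connectivity))
}

#' Fill interior holes of a binary mask
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  out <- cpp_fill_holes(mask)
  mode(out) <- "logical"
  out
}

#' Euclidean distance (pixels) from every pixel to the nearest TRUE pixel
#' @param target logical matrix.
#' @return numeric matrix of distances in pixel units.
#' @export
distance_to <- function(target) {
  stopifnot(is.matrix(target))
  mode(target) <- "logical"
  target[is.na(target)] <- FALSE
  sqrt(cpp_edt_sq(target))
}

# Even-odd-rule point-in-polygon test, vectorized over points.
# px, py: point coordinates; poly: matrix with columns x, y (open ring).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from a single point to a closed polyline (open ring),
# treating consecutive vertices (and last->first) as segments.
dist_point_polyline <- function(px, py, poly, closed = TRUE) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  if (closed) {
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  } else {
    x2 <- x1[-1]; y2 <- y1[-1]
    x1 <- x1[-length(x1)]; y1 <- y1[-length(y1)]
  }
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# Pixel-center coordinate grids in um for an image of shape c(nrow, ncol).
pixel_grid_um <- function(shape, pixel_size_um) {
  list(
    x = matrix((seq_len(shape[2]) - 1) * pixel_size_um,
               nrow = shape[1], ncol = shape[2], byrow = TRUE),
    y = matrix((seq_len(shape[1]) - 1) * pixel_size_um,
               nrow = shape[1], ncol = shape[2])
  )
}
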