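# Minimal multi-page grayscale TIFF I/O (uncompressed, little-endian,
# 32-bit float samples). The environment provides no TIFF package, so this
# self-contained writer/reader covers the movie interchange contract; the
# files are plain baseline TIFF readable by ImageJ/tifffile.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write a grayscale stack as a multi-page float32 TIFF
#'
#' @param x numeric matrix (one page) or rows x cols x frames array.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  ny <- dim(x)[1]; nx <- dim(x)[2]; np <- dim(x)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  data_bytes <- as.numeric(ny) * nx * 4
  first_ifd <- 8 + data_bytes * np
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (p in seq_len(np))   # scanline order: rows top to bottom
    writeBin(as.numeric(t(x[, , p])), con, size = 4, endian = "little")
  n_entries <- 10L
  ifd_size <- 2 + 12 * n_entries + 4
  for (p in seq_len(np)) {
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3L) {      # SHORT, left-justified in the 4-byte slot
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256, 4, 1, nx)
    entry(257, 4, 1, ny)
    entry(258, 3, 1, 32)
    entry(259, 3, 1, 1)
    entry(262, 3, 1, 1)
    entry(273, 4, 1, 8 + data_bytes * (p - 1))
    entry(277, 3, 1, 1)
    entry(278, 4, 1, ny)
    entry(279, 4, 1, data_bytes)
    entry(339, 3, 1, 3)
    next_ifd <- if (p < np) first_ifd + p * ifd_size else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed little-endian grayscale pages with float32 or
#' uint8/uint16 samples in one or more strips.
#'
#' @param path TIFF file.
#' @return rows x cols x frames numeric array.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stop("read_tiff: only little-endian TIFF supported")
  if (u16(2) != 42L) stop("read_tiff: not a TIFF file")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      # value(s): SHORT(3) 2 bytes each, LONG(4) 4 bytes each
      vsize <- if (type == 3L) 2L else 4L
      voff <- if (count * vsize <= 4) off + 8 else u32(off + 8)
      vals <- vapply(seq_len(count), function(i)
        if (type == 3L) u16(voff + (i - 1) * 2) else u32(voff + (i - 1) * 4),
        numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    gettag <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    nx <- gettag(256); ny <- gettag(257)
    bits <- gettag(258, 1)[1]
    if (gettag(259, 1) != 1) stop("read_tiff: compressed TIFF not supported")
    fmt <- gettag(339, 1)[1]
    offs <- gettag(273); counts <- gettag(279)
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw_all[(offs[i] + 1):(offs[i] + counts[i])]), use.names = FALSE)
    vals <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = nx * ny, size = 4, endian = "little")
    } else if (bits == 16) {
      readBin(buf, "integer", n = nx * ny, size = 2, signed = FALSE,
              endian = "little")
    } else if (bits == 8) {
      as.integer(buf)
    } else stop("read_tiff: unsupported sample layout (bits=", bits,
                ", format=", fmt, ")")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
    ifd <- u32(ifd + 2 + n * 12)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(0, dim = c(ny, nx, length(pages)))
  for (p in seq_along(pages)) out[, , p] <- pages[[p]]
  out
}
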