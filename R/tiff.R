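# Minimal baseline TIFF support (uncompressed grayscale, little-endian).
# No TIFF package ships with the installed R stack, so the image-stack
# interface implements the small subset of the format it needs: multi-page,
# 8- or 16-bit, single strip per page, no compression.

u16_raw <- function(v) as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256,
                         (v %/% 65536) %% 256, (v %/% 16777216) %% 256)))
}
ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value left-justified in the 4-byte slot
  val <- if (type == 3L) c(u16_raw(value), as.raw(c(0, 0))) else u32_raw(value)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val)
}

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' @param images A single integer matrix or a list of matrices (one page per
#'   cell); values are clamped to \[0, 65535\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2A, 0x00)), con) # "II", magic 42
  offset <- 8
  writeBin(u32_raw(offset), con) # first IFD directly after header
  n <- length(images)
  for (i in seq_len(n)) {
    img <- images[[i]]
    h <- nrow(img); w <- ncol(img)
    n_entries <- 8L
    ifd_size <- 2 + n_entries * 12 + 4
    data_offset <- offset + ifd_size
    n_bytes <- 2 * h * w
    entries <- c(
      ifd_entry(256L, 3L, 1L, w),            # ImageWidth
      ifd_entry(257L, 3L, 1L, h),            # ImageLength
      ifd_entry(258L, 3L, 1L, 16L),          # BitsPerSample
      ifd_entry(259L, 3L, 1L, 1L),           # Compression: none
      ifd_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
      ifd_entry(273L, 4L, 1L, data_offset),  # StripOffsets
      ifd_entry(278L, 3L, 1L, h),            # RowsPerStrip
      ifd_entry(279L, 4L, 1L, n_bytes)       # StripByteCounts
    )
    next_ifd <- if (i < n) data_offset + n_bytes else 0
    writeBin(u16_raw(n_entries), con)
    writeBin(entries, con)
    writeBin(u32_raw(next_ifd), con)
    v <- pmin(pmax(round(as.vector(t(img))), 0), 65535) # row-major pixel order
    writeBin(u16_raw(v), con)
    offset <- data_offset + n_bytes
  }
  invisible(path)
}

read_uint <- function(raw, pos, n_bytes) {
  sum(as.numeric(raw[pos:(pos + n_bytes - 1L)]) * 256^(0:(n_bytes - 1L)))
}

#' Read a multi-page grayscale TIFF into a list of integer matrices
#'
#' Supports the subset written by [write_tiff_stack()]: little-endian,
#' uncompressed, 8- or 16-bit grayscale, one or more strips per page.
#'
#' @param path TIFF file path.
#' @return List of integer matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8 || raw[[1]] != as.raw(0x49) || raw[[2]] != as.raw(0x49) ||
      read_uint(raw, 3, 2) != 42) {
    stop_erfrag("not a little-endian TIFF file.", "erfrag_io_error")
  }
  ifd_offset <- read_uint(raw, 5, 4)
  pages <- list()
  while (ifd_offset != 0) {
    base <- ifd_offset + 1 # raw vector is 1-based
    n_entries <- read_uint(raw, base, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      p <- base + 2 + (e - 1) * 12
      tag <- read_uint(raw, p, 2)
      type <- read_uint(raw, p + 2, 2)
      count <- read_uint(raw, p + 4, 4)
      size <- c(`1` = 1, `3` = 2, `4` = 4)[[as.character(type)]]
      if (is.null(size)) next
      vp <- if (count * size <= 4) p + 8 else read_uint(raw, p + 8, 4) + 1
      tags[[as.character(tag)]] <- vapply(seq_len(count), function(k)
        read_uint(raw, vp + (k - 1) * size, size), numeric(1))
    }
    w <- tags[["256"]][[1]]; h <- tags[["257"]][[1]]
    bits <- if (!is.null(tags[["258"]])) tags[["258"]][[1]] else 1
    if (!is.null(tags[["259"]]) && tags[["259"]][[1]] != 1) {
      stop_erfrag("compressed TIFF pages are not supported.", "erfrag_io_error")
    }
    if (!bits %in% c(8, 16)) {
      stop_erfrag("only 8- and 16-bit grayscale TIFF pages are supported.",
                  "erfrag_io_error")
    }
    offsets <- tags[["273"]]; counts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offsets), function(s)
      raw[(offsets[[s]] + 1):(offsets[[s]] + counts[[s]])]))
    vals <- if (bits == 16) {
      as.numeric(bytes[c(TRUE, FALSE)]) + 256 * as.numeric(bytes[c(FALSE, TRUE)])
    } else {
      as.numeric(bytes)
    }
    pages[[length(pages) + 1L]] <- matrix(as.integer(vals), nrow = h, byrow = TRUE)
    ifd_offset <- read_uint(raw, base + 2 + n_entries * 12, 4)
  }
  pages
}
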