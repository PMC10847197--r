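# Minimal baseline TIFF codec: little-endian, uncompressed, single-sample
# 16-bit unsigned grayscale, multi-page. This is the interchange subset used
# for serial-section channel stacks; no pre-installed R package reads TIFF in
# this environment, so the subset is implemented here and cross-checked
# against an external reference reader in the test suite.

.tiff_u16_bytes <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))  # lo, hi per value
}

.tiff_u32_bytes <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

# one 12-byte IFD entry; type 3 = SHORT, 4 = LONG; count always 1 here
.tiff_entry <- function(tag, type, value) {
  c(.tiff_u16_bytes(tag), .tiff_u16_bytes(type), .tiff_u32_bytes(1),
    if (type == 3L) c(.tiff_u16_bytes(value), as.raw(c(0, 0))) else .tiff_u32_bytes(value))
}

#' Write a section stack channel as a multi-page 16-bit TIFF
#'
#' Page index equals section index; intensities are clamped to the unsigned
#' 16-bit range and rounded (storage is 16-bit on disk, floating point in
#' memory).
#'
#' @param volume numeric array H x W x S (or H x W for a single section).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(volume, path) {
  if (length(dim(volume)) == 2) dim(volume) <- c(dim(volume), 1L)
  stopifnot(length(dim(volume)) == 3)
  volume <- pmin(pmax(round(volume), 0), 65535)
  H <- dim(volume)[1]; W <- dim(volume)[2]; S <- dim(volume)[3]
  nbytes_page <- 2 * H * W
  n_entries <- 9L
  ifd_size <- 2 + 12 * n_entries + 4

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.tiff_u16_bytes(42L), con)
  first_ifd <- 8 + nbytes_page
  writeBin(.tiff_u32_bytes(first_ifd), con)

  offset <- 8
  for (s in seq_len(S)) {
    # pixel data: row-major strips (TIFF raster order), one strip per page
    page <- t(volume[, , s])
    writeBin(.tiff_u16_bytes(as.vector(page)), con)
    strip_offset <- offset
    ifd_offset <- offset + nbytes_page
    next_ifd <- if (s < S) ifd_offset + ifd_size + nbytes_page else 0
    writeBin(.tiff_u16_bytes(n_entries), con)
    writeBin(c(
      .tiff_entry(256L, 4L, W),            # ImageWidth
      .tiff_entry(257L, 4L, H),            # ImageLength
      .tiff_entry(258L, 3L, 16L),          # BitsPerSample
      .tiff_entry(259L, 3L, 1L),           # Compression: none
      .tiff_entry(262L, 3L, 1L),           # Photometric: BlackIsZero
      .tiff_entry(273L, 4L, strip_offset), # StripOffsets
      .tiff_entry(277L, 3L, 1L),           # SamplesPerPixel
      .tiff_entry(278L, 4L, H),            # RowsPerStrip
      .tiff_entry(279L, 4L, nbytes_page)   # StripByteCounts
    ), con)
    writeBin(.tiff_u32_bytes(next_ifd), con)
    offset <- ifd_offset + ifd_size
  }
  invisible(path)
}

.tiff_read_u16 <- function(raw, pos, n = 1) {
  readBin(raw[pos:(pos + 2 * n - 1)], "integer", n = n, size = 2,
          signed = FALSE, endian = "little")
}

.tiff_read_u32 <- function(raw, pos, n = 1) {
  lo <- .tiff_read_u16(raw, pos, 2 * n)
  lo[seq(1, 2 * n, 2)] + 65536 * lo[seq(2, 2 * n, 2)]
}

#' Read a multi-page TIFF into an H x W x S array
#'
#' Supports the baseline subset written by [write_tiff_stack()]: little-endian,
#' uncompressed, 16-bit (or 8-bit) unsigned grayscale, any strip layout.
#'
#' @param path TIFF file path.
#' @return numeric array H x W x S.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || .tiff_read_u16(raw, 3) != 42L)
    stop("read_tiff_stack: not a little-endian TIFF file: ", path)
  ifd <- .tiff_read_u32(raw, 5)
  pages <- list()
  while (ifd != 0) {
    n_entries <- .tiff_read_u16(raw, ifd + 1)
    tags <- list()
    for (i in seq_len(n_entries)) {
      p <- ifd + 2 + 12 * (i - 1) + 1
      tag <- .tiff_read_u16(raw, p)
      type <- .tiff_read_u16(raw, p + 2)
      count <- .tiff_read_u32(raw, p + 4)
      size <- c(1, 1, 2, 4, 8)[type]
      vpos <- if (count * size <= 4) p + 8 else .tiff_read_u32(raw, p + 8) + 1
      val <- if (type == 3L) .tiff_read_u16(raw, vpos, count)
             else if (type == 4L) .tiff_read_u32(raw, vpos, count)
             else NULL
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("read_tiff_stack: missing required tag ", tag)
        default
      } else v
    }
    W <- need(256); H <- need(257)
    bits <- need(258, 1L)[1]
    if (!bits %in% c(8L, 16L))
      stop("read_tiff_stack: unsupported bit depth ", bits)
    if (need(259, 1L)[1] != 1L)
      stop("read_tiff_stack: compressed TIFF not supported")
    if (need(277, 1L)[1] != 1L)
      stop("read_tiff_stack: multi-sample TIFF not supported")
    offs <- need(273); counts <- need(279)
    vals <- unlist(lapply(seq_along(offs), function(i) {
      bytes <- raw[(offs[i] + 1):(offs[i] + counts[i])]
      if (bits == 16L) readBin(bytes, "integer", n = counts[i] / 2, size = 2,
                               signed = FALSE, endian = "little")
      else as.integer(bytes)
    }))
    if (length(vals) != H * W)
      stop("read_tiff_stack: strip data does not match page dimensions")
    pages[[length(pages) + 1]] <- t(matrix(vals, nrow = W, ncol = H))  # raster order
    ifd <- .tiff_read_u32(raw, ifd + 2 + 12 * n_entries + 1)
    if (ifd != 0) ifd <- ifd + 0  # keep numeric
  }
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) arr[, , s] <- pages[[s]]
  arr
}
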