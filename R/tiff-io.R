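# Minimal baseline TIFF codec (little-endian, uncompressed, single-sample
# grayscale). Microscopy stacks in this package are plain multi-page TIFFs;
# pixel types supported: uint8, uint16 and IEEE float32. One strip per page is
# written; readers accept multiple strips.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Write a stack of images as a multi-page TIFF
#'
#' @param frames list of numeric matrices (pages, all the same size) or an
#'   `H x W x T` array.
#' @param path output file path.
#' @param type pixel type: `"float32"` (default), `"uint16"` or `"uint8"`.
#'   Integer types round and clamp to the representable range.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, type = c("float32", "uint16", "uint8")) {
  type <- match.arg(type)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop_fretkit("no frames to write")
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  for (f in frames)
    if (nrow(f) != h || ncol(f) != w) stop_fretkit("all frames must share dimensions")

  bpp <- switch(type, uint8 = 1L, uint16 = 2L, float32 = 4L)
  bits <- 8L * bpp
  fmt <- if (type == "float32") 3L else 1L
  data_bytes <- h * w * bpp
  ifd_bytes <- 2L + 10L * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + data_bytes, con, size = 4, endian = "little")  # first IFD follows page-1 data

  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  entry <- function(tag, typ, count, value) {
    w2(tag); w2(typ); w4(count)
    if (typ == 3L) { w2(value); w2(0L) } else w4(value)
  }

  n <- length(frames)
  offset <- 8L
  for (i in seq_len(n)) {
    data_off <- offset
    ifd_off <- data_off + data_bytes
    v <- as.vector(t(frames[[i]]))          # TIFF scanlines are row-major
    if (type == "float32") {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else {
      top <- 2^bits - 1
      v <- pmin(pmax(round(v), 0), top)
      if (type == "uint16") v <- ifelse(v > 32767, v - 65536, v)  # two's complement
      if (type == "uint8") v <- ifelse(v > 127, v - 256, v)
      writeBin(as.integer(v), con, size = bpp, endian = "little")
    }
    w2(10L)
    entry(256L, 4L, 1L, w)                  # ImageWidth
    entry(257L, 4L, 1L, h)                  # ImageLength
    entry(258L, 3L, 1L, bits)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)           # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, h)                  # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)         # StripByteCounts
    entry(339L, 3L, 1L, fmt)                # SampleFormat
    # the next page's IFD sits after that page's pixel data
    w4(if (i < n) ifd_off + ifd_bytes + data_bytes else 0L)
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

#' Read a multi-page TIFF into a list of matrices
#'
#' Supports the subset this package writes (uncompressed little- or big-endian
#' grayscale, 8/16-bit unsigned or 32-bit float, strip layout).
#'
#' @param path TIFF file path.
#' @return list of numeric matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop_fretkit("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop_fretkit("not a TIFF file: ", path)
  int_at <- function(off, size, n = 1L, signed = FALSE) {
    # readBin only honours signed= for 1- and 2-byte ints; 4-byte reads are
    # signed, fine for sane file offsets (< 2 GiB)
    readBin(raw_all[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, endian = endian,
            signed = if (size <= 2L) signed else TRUE)
  }
  if (int_at(2L, 2L) != 42L) stop_fretkit("not a TIFF file: ", path)

  read_values <- function(off, typ, count) {
    size <- TIFF_TYPE_SIZES[[as.character(typ)]]
    total <- size * count
    voff <- if (total <= 4L) off + 8L else int_at(off + 8L, 4L)
    if (typ %in% c(1L, 3L, 4L)) int_at(voff, size, count, signed = FALSE)
    else if (typ == 11L)
      readBin(raw_all[(voff + 1L):(voff + total)], "double", n = count,
              size = 4L, endian = endian)
    else int_at(voff, size, count, signed = TRUE)
  }

  pages <- list()
  ifd_off <- int_at(4L, 4L)
  while (ifd_off != 0L) {
    n_entries <- int_at(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (e - 1L) * 12L
      tag <- int_at(eoff, 2L)
      typ <- int_at(eoff + 2L, 2L)
      count <- int_at(eoff + 4L, 4L)
      tags[[as.character(tag)]] <- read_values(eoff, typ, count)
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (is.null(w) || is.null(h)) stop_fretkit("TIFF page missing dimensions")
    if ((tags[["259"]] %||% 1L) != 1L)
      stop_fretkit("compressed TIFF not supported; re-save uncompressed")
    if ((tags[["277"]] %||% 1L) != 1L)
      stop_fretkit("only single-sample grayscale TIFF supported")
    bits <- tags[["258"]] %||% 8L
    fmt <- tags[["339"]] %||% 1L
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offs)) stop_fretkit("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep(w * h * bits / 8L / length(offs), length(offs))
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[(offs[s] + 1L):(offs[s] + counts[s])])
    v <- if (fmt == 3L) {
      readBin(buf, "double", n = w * h, size = 4L, endian = endian)
    } else {
      readBin(buf, "integer", n = w * h, size = bits / 8L, endian = endian,
              signed = bits > 16L)
    }
    if (fmt == 1L && bits <= 16L) v[v < 0] <- v[v < 0] + 2^bits  # undo sign
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- int_at(ifd_off + 2L + n_entries * 12L, 4L)
  }
  pages
}
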