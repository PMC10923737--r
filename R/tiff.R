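# Minimal single-band 32-bit-float TIFF writer/reader (uncompressed,
# little-endian, one strip on write; multi-strip accepted on read). Installed
# image packages clamp float samples to [0,1], which cannot represent LST in
# Kelvin or NDVI in [-1,1], hence this self-contained implementation.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

tif_write_frame <- function(mat, path) {
  rows <- nrow(mat); cols <- ncol(mat)
  nbytes <- rows * cols * 4L
  entries <- list(   # tag, type (3 short / 4 long), count, value
    c(256L, 4L, 1L, cols),
    c(257L, 4L, 1L, rows),
    c(258L, 3L, 1L, 32L),
    c(259L, 3L, 1L, 1L),
    c(262L, 3L, 1L, 1L),
    c(273L, 4L, 1L, NA),                 # data offset, patched below
    c(277L, 3L, 1L, 1L),
    c(278L, 4L, 1L, rows),
    c(279L, 4L, 1L, nbytes),
    c(339L, 3L, 1L, 3L)
  )
  ifd_size <- 2L + 12L * length(entries) + 4L
  data_offset <- 8L + ifd_size
  entries[[6]][4] <- data_offset
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")     # first IFD offset
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2L, endian = "little")
    writeBin(e[2], con, size = 2L, endian = "little")
    writeBin(e[3], con, size = 4L, endian = "little")
    if (e[2] == 3L) {   # SHORT: value left-justified in 4-byte field
      writeBin(e[4], con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(e[4], con, size = 4L, endian = "little")
    }
  }
  writeBin(0L, con, size = 4L, endian = "little")     # no next IFD
  # pixel data, row-major from the top row; NA stored as NaN
  v <- as.numeric(t(mat))
  v[is.na(v)] <- NaN
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}

tif_read_frame <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  get_int <- function(off, size, n = 1L)
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)
  if (get_int(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- get_int(4L, 4L)
  n_entries <- get_int(ifd, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + 12L * (i - 1L)
    tag <- get_int(off, 2L)
    type <- get_int(off + 2L, 2L)
    count <- get_int(off + 4L, 4L)
    tsize <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
    if (!type %in% c(3L, 4L)) next   # only SHORT/LONG tags are relevant
    if (tsize * count <= 4L) {
      val <- get_int(off + 8L, tsize, count)
    } else {
      val <- get_int(get_int(off + 8L, 4L), tsize, count)
    }
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  if (need(259L, 1L) != 1L)
    stop("compressed TIFF not supported: ", path)
  if (need(258L) != 32L || need(339L, 1L) != 3L)
    stop("only 32-bit IEEE float TIFF supported: ", path)
  if (need(277L, 1L) != 1L)
    stop("only single-band TIFF supported: ", path)
  cols <- need(256L); rows <- need(257L)
  offsets <- need(273L); counts <- need(279L)
  vals <- numeric(0)
  for (i in seq_along(offsets)) {
    vals <- c(vals, readBin(raw[(offsets[i] + 1L):(offsets[i] + counts[i])],
                            "numeric", n = counts[i] / 4L, size = 4L,
                            endian = endian))
  }
  if (length(vals) != rows * cols)
    stop("TIFF pixel count mismatch in ", path)
  t(matrix(vals, nrow = cols, ncol = rows))   # stored row-major
}
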