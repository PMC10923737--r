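# Minimal NetCDF classic (CDF-1) writer/reader, sufficient for single-variable
# (time, y, x) float cubes with CF-style _FillValue and a CF time coordinate.
# Big-endian throughout per the classic format; all dimensions fixed-size.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L; NC_INT <- 4L
NC_FLOAT <- 5L; NC_DOUBLE <- 6L
NC_DIMENSION <- 10L; NC_VARIABLE <- 11L; NC_ATTRIBUTE <- 12L
NC_FILL_FLOAT <- 9.9692099683868690e+36

nc_pad4 <- function(n) as.integer((4 - n %% 4) %% 4)

nc_put_int <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                        endian = "big")
nc_put_name <- function(con, name) {
  raw <- charToRaw(name)
  nc_put_int(con, length(raw))
  writeBin(raw, con)
  pad <- nc_pad4(length(raw))
  if (pad > 0) writeBin(raw(pad), con)
}
nc_put_att <- function(con, name, value) {
  nc_put_name(con, name)
  if (is.character(value)) {
    raw <- charToRaw(value)
    nc_put_int(con, NC_CHAR); nc_put_int(con, length(raw))
    writeBin(raw, con)
    pad <- nc_pad4(length(raw))
    if (pad > 0) writeBin(raw(pad), con)
  } else if (is.integer(value)) {
    nc_put_int(con, NC_INT); nc_put_int(con, length(value))
    nc_put_int(con, value)
  } else {
    nc_put_int(con, NC_FLOAT); nc_put_int(con, length(value))
    writeBin(as.numeric(value), con, size = 4L, endian = "big")
  }
}
nc_put_att_list <- function(con, atts) {
  if (length(atts) == 0) {
    nc_put_int(con, 0L); nc_put_int(con, 0L)
  } else {
    nc_put_int(con, NC_ATTRIBUTE); nc_put_int(con, length(atts))
    for (nm in names(atts)) nc_put_att(con, nm, atts[[nm]])
  }
}

# vars: list of list(name, dimids (0-based), atts, type, data)
nc_serialize <- function(dims, gatts, vars, begins) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con); writeBin(as.raw(1L), con)
  nc_put_int(con, 0L)                       # numrecs (no record dimension)
  nc_put_int(con, NC_DIMENSION); nc_put_int(con, length(dims))
  for (nm in names(dims)) { nc_put_name(con, nm); nc_put_int(con, dims[[nm]]) }
  nc_put_att_list(con, gatts)
  nc_put_int(con, NC_VARIABLE); nc_put_int(con, length(vars))
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    nc_put_name(con, v$name)
    nc_put_int(con, length(v$dimids))
    for (d in v$dimids) nc_put_int(con, d)
    nc_put_att_list(con, v$atts)
    nc_put_int(con, v$type)
    sz <- nc_type_size(v$type) * prod(unlist(dims)[v$dimids + 1L])
    nc_put_int(con, sz + nc_pad4(sz))
    nc_put_int(con, begins[i])
  }
  rawConnectionValue(con)
}

nc_type_size <- function(type) {
  c(1L, 1L, 2L, 4L, 4L, 8L)[type]
}

nc_write_file <- function(path, dims, gatts, vars) {
  header <- nc_serialize(dims, gatts, vars, rep(0L, length(vars)))
  begins <- integer(length(vars))
  off <- length(header)
  for (i in seq_along(vars)) {
    begins[i] <- off
    sz <- nc_type_size(vars[[i]]$type) *
      prod(unlist(dims)[vars[[i]]$dimids + 1L])
    off <- off + sz + nc_pad4(sz)
  }
  header <- nc_serialize(dims, gatts, vars, begins)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (v in vars) {
    if (v$type == NC_INT) {
      nc_put_int(con, v$data)
    } else if (v$type == NC_FLOAT) {
      writeBin(as.numeric(v$data), con, size = 4L, endian = "big")
      sz <- 4L * length(v$data)
      if (nc_pad4(sz) > 0) writeBin(raw(nc_pad4(sz)), con)
    } else if (v$type == NC_DOUBLE) {
      writeBin(as.numeric(v$data), con, size = 8L, endian = "big")
    } else stop("unsupported variable type for writing: ", v$type)
  }
  invisible(path)
}

# --- reader ------------------------------------------------------------------

nc_reader <- function(raw) {
  env <- new.env()
  env$raw <- raw; env$pos <- 1L
  env
}
rd_bytes <- function(rd, n) {
  out <- rd$raw[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + as.integer(n)
  out
}
rd_int <- function(rd, n = 1L)
  readBin(rd_bytes(rd, 4L * n), "integer", n = n, size = 4L, endian = "big")
rd_name <- function(rd) {
  len <- rd_int(rd)
  nm <- rawToChar(rd_bytes(rd, len))
  if (nc_pad4(len) > 0) rd_bytes(rd, nc_pad4(len))
  nm
}
rd_att_values <- function(rd, type, n) {
  if (type == NC_CHAR) {
    v <- rawToChar(rd_bytes(rd, n))
    if (nc_pad4(n) > 0) rd_bytes(rd, nc_pad4(n))
    v
  } else if (type == NC_INT) {
    rd_int(rd, n)
  } else if (type == NC_FLOAT) {
    v <- readBin(rd_bytes(rd, 4L * n), "numeric", n = n, size = 4L,
                 endian = "big")
    sz <- 4L * n
    if (nc_pad4(sz) > 0) rd_bytes(rd, nc_pad4(sz))
    v
  } else if (type == NC_DOUBLE) {
    readBin(rd_bytes(rd, 8L * n), "numeric", n = n, size = 8L, endian = "big")
  } else if (type %in% c(NC_BYTE, NC_SHORT)) {
    sz <- nc_type_size(type) * n
    v <- readBin(rd_bytes(rd, sz), "integer", n = n,
                 size = nc_type_size(type), endian = "big")
    if (nc_pad4(sz) > 0) rd_bytes(rd, nc_pad4(sz))
    v
  } else stop("unknown attribute type ", type)
}
rd_att_list <- function(rd) {
  tag <- rd_int(rd); nelems <- rd_int(rd)
  if (tag == 0L && nelems == 0L) return(list())
  if (tag != NC_ATTRIBUTE) stop("malformed NetCDF attribute list")
  out <- list()
  for (i in seq_len(nelems)) {
    nm <- rd_name(rd)
    type <- rd_int(rd); n <- rd_int(rd)
    out[[nm]] <- rd_att_values(rd, type, n)
  }
  out
}

# Parse a classic-format NetCDF file into dims/atts/vars (+ data).
nc_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4L || rawToChar(raw[1:3]) != "CDF")
    stop("not a NetCDF classic file: ", path)
  version <- as.integer(raw[4])
  if (!version %in% c(1L, 2L))
    stop("unsupported NetCDF variant (only classic CDF-1/CDF-2): ", path)
  rd <- nc_reader(raw)
  rd$pos <- 5L
  numrecs <- rd_int(rd)
  tag <- rd_int(rd); ndims <- rd_int(rd)
  dims <- list()
  if (tag == NC_DIMENSION) {
    for (i in seq_len(ndims)) {
      nm <- rd_name(rd)        # must be read before the length
      dims[[nm]] <- rd_int(rd)
    }
  }
  gatts <- rd_att_list(rd)
  tag <- rd_int(rd); nvars <- rd_int(rd)
  vars <- list()
  if (tag == NC_VARIABLE) {
    for (i in seq_len(nvars)) {
      nm <- rd_name(rd)
      nd <- rd_int(rd)
      dimids <- if (nd > 0) rd_int(rd, nd) else integer(0)
      atts <- rd_att_list(rd)
      type <- rd_int(rd)
      vsize <- rd_int(rd)
      begin <- if (version == 2L) {
        hi <- rd_int(rd); lo <- rd_int(rd)
        hi * 2^32 + (lo %% 2^32)
      } else rd_int(rd)
      vars[[nm]] <- list(name = nm, dimids = dimids, atts = atts,
                         type = type, begin = begin)
    }
  }
  dlen <- unlist(dims)
  if (any(dlen == 0))
    stop("record (unlimited) dimensions are not supported by this reader")
  for (nm in names(vars)) {
    v <- vars[[nm]]
    shape <- dlen[v$dimids + 1L]
    n <- prod(shape)
    sub <- nc_reader(raw); sub$pos <- as.integer(v$begin) + 1L
    vars[[nm]]$data <- if (v$type == NC_CHAR) {
      rawToChar(rd_bytes(sub, n))
    } else if (v$type %in% c(NC_BYTE, NC_SHORT, NC_INT)) {
      readBin(rd_bytes(sub, nc_type_size(v$type) * n), "integer", n = n,
              size = nc_type_size(v$type), endian = "big")
    } else {
      readBin(rd_bytes(sub, nc_type_size(v$type) * n), "numeric", n = n,
              size = nc_type_size(v$type), endian = "big")
    }
    vars[[nm]]$shape <- shape
  }
  list(dims = dims, gatts = gatts, vars = vars)
}
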