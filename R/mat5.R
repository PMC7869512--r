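# Minimal MAT v5 (Level 5) codec: little-endian, uncompressed, real double
# matrices only. Enough to exchange DiaTrack-style trace containers and to
# build test fixtures in code; anything else (compressed elements, cells,
# structs, complex data) is rejected with a clear error.

MI_INT8 <- 1L
MI_INT32 <- 5L
MI_UINT32 <- 6L
MI_DOUBLE <- 9L
MI_COMPRESSED <- 15L
MI_MATRIX <- 14L
MX_DOUBLE_CLASS <- 6L

pad8 <- function(n) (8L - n %% 8L) %% 8L

#' Write double matrices to a MAT v5 file
#'
#' @param vars named list of real numeric matrices (or vectors, stored as
#'   column matrices).
#' @param path destination file.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
write_mat5 <- function(vars, path) {
  if (length(vars) == 0 || is.null(names(vars)) || any(names(vars) == "")) {
    stop("`vars` must be a non-empty named list", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, written by track4d")
  hd <- charToRaw(header)
  hd <- c(hd, rep(as.raw(0x20), 116 - length(hd)))
  writeBin(hd, con)
  writeBin(raw(8), con)                                   # subsys offset
  writeBin(as.integer(0x0100), con, size = 2, endian = "little")
  writeBin(charToRaw("IM"), con)                          # endian indicator
  for (nm in names(vars)) {
    m <- vars[[nm]]
    if (!is.numeric(m)) stop("only numeric variables are supported", call. = FALSE)
    if (!is.matrix(m)) m <- matrix(m, ncol = 1)
    name_raw <- charToRaw(nm)
    n_name_pad <- pad8(length(name_raw))
    body_bytes <- 16L +                                   # array flags
      16L +                                               # dimensions (2)
      8L + length(name_raw) + n_name_pad +                # name
      8L + 8L * length(m)                                 # real data
    writeBin(c(MI_MATRIX, body_bytes), con, size = 4, endian = "little")
    writeBin(c(MI_UINT32, 8L), con, size = 4, endian = "little")
    writeBin(c(MX_DOUBLE_CLASS, 0L), con, size = 4, endian = "little")
    writeBin(c(MI_INT32, 8L), con, size = 4, endian = "little")
    writeBin(c(nrow(m), ncol(m)), con, size = 4, endian = "little")
    writeBin(c(MI_INT8, length(name_raw)), con, size = 4, endian = "little")
    writeBin(name_raw, con)
    if (n_name_pad > 0) writeBin(raw(n_name_pad), con)
    writeBin(c(MI_DOUBLE, 8L * length(m)), con, size = 4, endian = "little")
    writeBin(as.double(m), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_mat5_tag <- function(buf, pos) {
  word <- readBin(buf[pos + 1:4], "integer", size = 4, endian = "little")
  small_size <- bitwShiftR(bitwAnd(word, -65536L), 16)
  if (small_size != 0L) {
    list(type = bitwAnd(word, 65535L), size = small_size, data_at = pos + 4L,
         next_at = pos + 8L)
  } else {
    size <- readBin(buf[pos + 5:8], "integer", size = 4, endian = "little")
    list(type = word, size = size, data_at = pos + 8L,
         next_at = pos + 8L + size + pad8(size))
  }
}

#' Read double matrices from a MAT v5 file
#'
#' @param path MAT v5 file (little-endian, uncompressed double matrices).
#' @return Named list of numeric matrices.
#' @keywords internal
#' @export
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128) stop("not a MAT v5 file (truncated header)", call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") {
    stop("unsupported MAT file (expected little-endian v5)", call. = FALSE)
  }
  out <- list()
  pos <- 128L
  while (pos < length(buf)) {
    tag <- read_mat5_tag(buf, pos)
    if (tag$type == MI_COMPRESSED) {
      stop("compressed MAT elements are not supported", call. = FALSE)
    }
    if (tag$type != MI_MATRIX) {
      stop(sprintf("unsupported top-level MAT element type %d", tag$type),
           call. = FALSE)
    }
    p <- tag$data_at
    flags <- read_mat5_tag(buf, p)
    cls <- bitwAnd(
      readBin(buf[flags$data_at + 1:4], "integer", size = 4, endian = "little"),
      255L
    )
    if (cls != MX_DOUBLE_CLASS) {
      stop("only double-precision matrices are supported", call. = FALSE)
    }
    p <- flags$next_at
    dims_el <- read_mat5_tag(buf, p)
    dims <- readBin(buf[dims_el$data_at + seq_len(dims_el$size)], "integer",
                    n = dims_el$size / 4L, size = 4, endian = "little")
    if (length(dims) != 2L) {
      stop("only 2D matrices are supported", call. = FALSE)
    }
    p <- dims_el$next_at
    name_el <- read_mat5_tag(buf, p)
    nm <- rawToChar(buf[name_el$data_at + seq_len(name_el$size)])
    p <- name_el$next_at
    data_el <- read_mat5_tag(buf, p)
    if (data_el$type != MI_DOUBLE) {
      stop("only uncompressed miDOUBLE data is supported", call. = FALSE)
    }
    vals <- readBin(buf[data_el$data_at + seq_len(data_el$size)], "double",
                    n = data_el$size / 8L, size = 8, endian = "little")
    out[[nm]] <- matrix(vals, nrow = dims[1], ncol = dims[2])
    pos <- tag$next_at
  }
  out
}
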