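# Minimal MAT v5 file support, sufficient for wave_clus-style files:
# named numeric arrays (any integer/float storage class), including
# zlib-compressed elements. Cell/struct/char variables are skipped with
# their names preserved as NULL entries. The v7.3 (HDF5) dialect is
# detected and rejected. Little-endian files only, which is what every
# mainstream writer produces.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

pad8 <- function(n) (8L - n %% 8L) %% 8L

read_mi_values <- function(buf, type, nbytes) {
  switch(as.character(type),
    "1" = as.numeric(readBin(buf, "integer", n = nbytes, size = 1, signed = TRUE)),
    "2" = as.numeric(readBin(buf, "integer", n = nbytes, size = 1, signed = FALSE)),
    "3" = as.numeric(readBin(buf, "integer", n = nbytes / 2, size = 2,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(buf, "integer", n = nbytes / 2, size = 2,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(buf, "integer", n = nbytes / 4, size = 4,
                             endian = "little")),
    "6" = as.numeric(readBin(buf, "integer", n = nbytes / 4, size = 4,
                             endian = "little")),
    "7" = readBin(buf, "double", n = nbytes / 4, size = 4, endian = "little"),
    "9" = readBin(buf, "double", n = nbytes / 8, size = 8, endian = "little"),
    stop("unsupported MAT data type ", type))
}

# Split a raw buffer into (type, data) sub-elements, handling the packed
# "small data element" form where type and size share the first 4 bytes.
parse_elements <- function(buf) {
  out <- list()
  pos <- 1L
  n <- length(buf)
  while (pos + 7L <= n) {
    first <- readBin(buf[pos:(pos + 3L)], "integer", size = 4, endian = "little")
    small_size <- bitwShiftR(bitwAnd(first, -65536L), 16)
    if (small_size != 0L) {
      type <- bitwAnd(first, 65535L)
      size <- bitwAnd(small_size, 65535L)
      data <- buf[(pos + 4L):(pos + 3L + size)]
      pos <- pos + 8L
    } else {
      type <- first
      size <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", size = 4,
                      endian = "little")
      data <- if (size > 0) buf[(pos + 8L):(pos + 7L + size)] else raw(0)
      pos <- pos + 8L + size + pad8(size)
    }
    out[[length(out) + 1L]] <- list(type = type, data = data, size = size)
  }
  out
}

parse_matrix_element <- function(buf) {
  sub <- parse_elements(buf)
  if (length(sub) < 3) stop("malformed MAT matrix element")
  flags <- readBin(sub[[1]]$data, "integer", n = 2, size = 4, endian = "little")
  cls <- bitwAnd(flags[1], 255L)
  dims <- readBin(sub[[2]]$data, "integer", n = sub[[2]]$size / 4, size = 4,
                  endian = "little")
  name <- rawToChar(sub[[3]]$data)
  if (!(cls %in% 6:13) || length(sub) < 4)   # numeric classes only
    return(list(name = name, value = NULL))
  vals <- read_mi_values(sub[[4]]$data, sub[[4]]$type, sub[[4]]$size)
  value <- if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else vals
  list(name = name, value = value)
}

#' Read numeric variables from a MAT v5 file
#'
#' @param path MAT-file path.
#' @return Named list of numeric matrices/vectors; non-numeric variables
#'   appear as `NULL` entries.
#' @seealso [read_waveclus_dataset()] for the benchmark-layout wrapper.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 128) stop("not a MAT v5 file: ", path)
  header <- rawToChar(buf[1:116])
  if (grepl("MATLAB 7.3", header, fixed = TRUE))
    stop("MAT v7.3 (HDF5) files are not supported; re-save as v5")
  endian <- rawToChar(buf[127:128])
  if (endian != "IM")
    stop("unsupported MAT-file (big-endian or not v5): ", path)
  elements <- parse_elements(buf[-(1:128)])
  vars <- list()
  for (el in elements) {
    if (el$type == MI_COMPRESSED) {
      inner <- parse_elements(memDecompress(el$data, type = "gzip"))
      for (iel in inner) {
        if (iel$type == MI_MATRIX) {
          v <- parse_matrix_element(iel$data)
          vars[v$name] <- list(v$value)
        }
      }
    } else if (el$type == MI_MATRIX) {
      v <- parse_matrix_element(el$data)
      vars[v$name] <- list(v$value)
    }
  }
  vars
}

mat5_matrix_raw <- function(name, value) {
  value <- as.matrix(value)
  dims <- dim(value)
  name_raw <- charToRaw(name)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # array flags
  w_int(MI_UINT32); w_int(8L); w_int(MX_DOUBLE_CLASS); w_int(0L)
  # dimensions
  w_int(MI_INT32); w_int(8L); w_int(dims[1]); w_int(dims[2])
  # name
  w_int(MI_INT8); w_int(length(name_raw))
  writeBin(name_raw, con)
  writeBin(raw(pad8(length(name_raw))), con)
  # real data (column-major doubles)
  w_int(MI_DOUBLE); w_int(8L * length(value))
  writeBin(as.numeric(value), con, size = 8, endian = "little")
  body <- rawConnectionValue(con)
  head <- rawConnection(raw(0), "wb")
  on.exit(close(head), add = TRUE)
  writeBin(as.integer(c(MI_MATRIX, length(body))), head, size = 4,
           endian = "little")
  c(rawConnectionValue(head), body)
}

#' Write numeric variables to a MAT v5 file
#'
#' @param vars Named list of numeric vectors/matrices (stored as doubles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by ldadp on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  desc_raw <- charToRaw(formatC(desc, width = -116))
  writeBin(desc_raw[1:116], con)
  writeBin(raw(8), con)                                   # subsystem offset
  writeBin(as.integer(256), con, size = 2, endian = "little")  # version
  writeBin(charToRaw("IM"), con)                          # endian indicator
  for (nm in names(vars)) writeBin(mat5_matrix_raw(nm, vars[[nm]]), con)
  invisible(path)
}
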