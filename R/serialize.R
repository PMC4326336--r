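# Binary index serialization. Layout (all integers little-endian):
#   magic "OFFSPOT1" (8 bytes), format version (u32),
#   PAM table: count (u32), then per pattern id (u32) + string,
#   genome metadata: count (u32), then per chromosome name string + length (u64),
#   Table A encoding tag (u32; 0 = sparse), occupied-prefix count (u64),
#     prefix codes (u64 each), offsets (count+1 u64),
#   Table B: record count (u64), packed words (u64 each).
# Strings are u32 length + raw bytes. 64-bit values are written as two u32
# halves, low first; all values fit below 2^53 so doubles carry them exactly.

.INDEX_MAGIC <- "OFFSPOT1"
.INDEX_VERSION <- 1

.write_u32 <- function(con, v) {
  v <- as.numeric(v)
  if (any(v < 0 | v >= 2^32)) stop("serialization error: u32 overflow")
  iv <- ifelse(v >= 2^31, v - 2^32, v)
  writeBin(as.integer(iv), con, size = 4L, endian = "little")
}

.read_u32 <- function(con, n) {
  r <- readBin(con, integer(), n = n, size = 4L, endian = "little")
  if (length(r) < n) stop("load error: truncated index file")
  r <- as.numeric(r)
  ifelse(r < 0, r + 2^32, r)
}

.write_u64 <- function(con, v) {
  v <- as.numeric(v)
  if (any(v < 0 | v >= 2^53)) stop("serialization error: u64 value above 2^53")
  lo <- v %% 2^32
  hi <- v %/% 2^32
  .write_u32(con, as.vector(rbind(lo, hi)))
}

.read_u64 <- function(con, n) {
  u <- .read_u32(con, 2L * n)
  idx <- seq_len(n)
  u[2L * idx - 1L] + u[2L * idx] * 2^32
}

.write_str <- function(con, s) {
  raw <- charToRaw(s)
  .write_u32(con, length(raw))
  writeBin(raw, con)
}

.read_str <- function(con) {
  len <- .read_u32(con, 1L)
  raw <- readBin(con, raw(), n = len)
  if (length(raw) < len) stop("load error: truncated index file")
  rawToChar(raw)
}

#' Save an off-target index to a binary file
#'
#' The file is self-describing: it carries the PAM pattern table and the
#' genome metadata, begins with a fixed magic string and a format version,
#' and stores Table B as little-endian 64-bit words.
#'
#' @param index an `offtarget_index` from [build_index()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_index()]
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "offtarget_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.INDEX_MAGIC), con)
  .write_u32(con, .INDEX_VERSION)
  .write_u32(con, length(index$pam_table))
  for (p in index$pam_table) {
    .write_u32(con, p$pam_id)
    .write_str(con, p$text)
  }
  .write_u32(con, length(index$chrom_names))
  for (i in seq_along(index$chrom_names)) {
    .write_str(con, index$chrom_names[i])
    .write_u64(con, index$chrom_lengths[i])
  }
  .write_u32(con, 0)                                # Table A encoding: sparse
  .write_u64(con, length(index$prefix_codes))
  if (length(index$prefix_codes)) .write_u64(con, index$prefix_codes)
  .write_u64(con, index$offsets)
  .write_u64(con, length(index$table_b))
  if (length(index$table_b)) .write_u64(con, index$table_b)
  invisible(path)
}

#' Load an off-target index from a binary file
#'
#' Verifies the magic string and format version before reading; corrupt or
#' truncated files raise a load error.
#'
#' @param path file written by [save_index()].
#' @return an `offtarget_index`.
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("load error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = nchar(.INDEX_MAGIC))
  if (length(magic) < nchar(.INDEX_MAGIC) ||
      !identical(rawToChar(magic), .INDEX_MAGIC)) {
    stop("load error: '", path, "' is not an off-target index (bad magic)")
  }
  version <- .read_u32(con, 1L)
  if (version != .INDEX_VERSION) {
    stop("load error: index format version ", version,
         " not supported (expected ", .INDEX_VERSION, ")")
  }
  npam <- .read_u32(con, 1L)
  pam_table <- vector("list", npam)
  for (i in seq_len(npam)) {
    id <- .read_u32(con, 1L)
    pam_table[[i]] <- parse_pam(.read_str(con), pam_id = id)
  }
  nchrom <- .read_u32(con, 1L)
  chrom_names <- character(nchrom)
  chrom_lengths <- numeric(nchrom)
  for (i in seq_len(nchrom)) {
    chrom_names[i] <- .read_str(con)
    chrom_lengths[i] <- .read_u64(con, 1L)
  }
  tag <- .read_u32(con, 1L)
  if (tag != 0) stop("load error: unknown Table A encoding tag ", tag)
  nprefix <- .read_u64(con, 1L)
  prefix_codes <- .read_u64(con, nprefix)
  offsets <- .read_u64(con, nprefix + 1L)
  nrec <- .read_u64(con, 1L)
  table_b <- .read_u64(con, nrec)
  if (utils::tail(offsets, 1L) != nrec) {
    stop("load error: offset table inconsistent with record count")
  }
  structure(list(
    prefix_codes = prefix_codes,
    offsets = offsets,
    table_b = table_b,
    pam_table = pam_table,
    chrom_names = chrom_names,
    chrom_lengths = chrom_lengths
  ), class = "offtarget_index")
}
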