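# On-disk container layout (format version 1), all integers little-endian:
#   bytes 0..5   magic "SRCOMP"
#   byte  6      format version (1)
#   byte  7      reserved (0)
#   u32          read length L
#   u64          total read count n
#   u32          block count B
# then per block:
#   u64          read count
#   u64          N count (ambiguous bases restored in this block)
#   u64          read stream bit count
#   u64          N stream bit count
#   raw          read stream, ceil(bits/8) bytes, zero-padded
#   raw          N stream, ceil(bits/8) bytes, zero-padded
# Blocks are independent: each restarts the delta baseline (its first read is
# encoded as r1 + 1) and numbers its G-ordinals locally.

.SRCOMP_MAGIC <- charToRaw("SRCOMP")
.SRCOMP_VERSION <- 1L

.u32_raw <- function(x) {
  x <- as.numeric(x)
  if (x < 0 || x >= 2^32) stop("u32 field out of range")
  if (x >= 2^31) x <- x - 2^32
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

.u64_raw <- function(x) {
  x <- as.numeric(x)
  if (x < 0 || x > 2^53) stop("count field out of exact range")
  c(.u32_raw(x %% 2^32), .u32_raw(x %/% 2^32))
}

.read_u32 <- function(con) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(v)) stop("corrupt file: truncated header")
  if (v < 0) v <- v + 2^32
  as.numeric(v)
}

.read_u64 <- function(con) {
  lo <- .read_u32(con)
  hi <- .read_u32(con)
  lo + hi * 2^32
}

.stream_bytes <- function(stream) {
  nb <- ceiling(as.numeric(stream$nbits) / 8)
  if (length(stream$bytes) != nb)
    stop("block stream byte length does not match its bit count")
  stream
}

#' Build one container block record
#'
#' @param read_count Number of reads encoded in the block.
#' @param n_count Number of ambiguous bases restored in the block.
#' @param read_stream,n_stream Lists with `bytes` (raw) and `nbits`, as
#'   produced by [encode_read_stream()] and the omega stream encoder.
#' @return Object of class `srcomp_block`.
#' @export
srcomp_block <- function(read_count, n_count, read_stream, n_stream) {
  structure(list(read_count = as.numeric(read_count),
                 n_count = as.numeric(n_count),
                 read_stream = .stream_bytes(read_stream),
                 n_stream = .stream_bytes(n_stream)),
            class = "srcomp_block")
}

#' Write a compressed container
#'
#' Deterministic byte layout (see the package vignette): header with magic,
#' version, read length and counts, then per-block counts and byte-aligned
#' omega bitstreams. The same blocks always produce byte-identical files.
#'
#' @param path Output file path.
#' @param blocks List of [srcomp_block()] records.
#' @param read_length Read length L (0 allowed for an empty container).
#' @param total_read_count Total reads; defaults to the sum over blocks.
#' @return Number of bytes written, invisibly.
#' @seealso [read_container()]
#' @export
write_container <- function(path, blocks, read_length,
                            total_read_count = NULL) {
  counts <- vapply(blocks, function(b) b$read_count, numeric(1))
  if (is.null(total_read_count)) total_read_count <- sum(counts)
  if (length(blocks) && sum(counts) != total_read_count)
    stop("block read counts do not sum to the total read count")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.SRCOMP_MAGIC, con)
  writeBin(as.raw(c(.SRCOMP_VERSION, 0L)), con)
  writeBin(.u32_raw(read_length), con)
  writeBin(.u64_raw(total_read_count), con)
  writeBin(.u32_raw(length(blocks)), con)
  written <- 8 + 4 + 8 + 4
  for (b in blocks) {
    stopifnot(inherits(b, "srcomp_block"))
    writeBin(.u64_raw(b$read_count), con)
    writeBin(.u64_raw(b$n_count), con)
    writeBin(.u64_raw(b$read_stream$nbits), con)
    writeBin(.u64_raw(b$n_stream$nbits), con)
    writeBin(b$read_stream$bytes, con)
    writeBin(b$n_stream$bytes, con)
    written <- written + 32 + length(b$read_stream$bytes) +
      length(b$n_stream$bytes)
  }
  invisible(written)
}

.check_padding <- function(bytes, nbits, what) {
  if (!length(bytes)) return(invisible())
  pad <- length(bytes) * 8 - nbits
  if (pad < 0 || pad >= 8)
    stop(sprintf("corrupt file: %s byte length inconsistent with bit count", what))
  if (pad > 0) {
    last <- as.integer(bytes[length(bytes)])
    if (last %% 2^pad != 0)
      stop(sprintf("corrupt file: nonzero padding bits in %s", what))
  }
  invisible()
}

.read_stream_payload <- function(con, nbits, what) {
  nb <- ceiling(nbits / 8)
  bytes <- readBin(con, "raw", n = nb)
  if (length(bytes) != nb)
    stop(sprintf("corrupt file: truncated %s", what))
  .check_padding(bytes, nbits, what)
  list(bytes = bytes, nbits = nbits)
}

#' Read and structurally validate a compressed container
#'
#' Checks the magic tag, format version, count consistency, stream lengths,
#' zero padding and absence of trailing bytes; payload bitstreams are read
#' into memory but not decoded.
#'
#' @param path Path to a container written by [write_container()].
#' @return Object of class `srcomp_container`: a list with `read_length`,
#'   `total_read_count`, `block_count` and `blocks`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) != 6L || !identical(magic, .SRCOMP_MAGIC))
    stop("not an srcomp container (bad magic tag): ", path)
  verres <- readBin(con, "raw", n = 2L)
  if (length(verres) != 2L) stop("corrupt file: truncated header")
  version <- as.integer(verres[1L])
  if (version != .SRCOMP_VERSION)
    stop("unsupported container format version ", version)
  read_length <- .read_u32(con)
  total <- .read_u64(con)
  nblocks <- .read_u32(con)
  blocks <- vector("list", nblocks)
  for (i in seq_len(nblocks)) {
    rc <- .read_u64(con)
    nc <- .read_u64(con)
    rbits <- .read_u64(con)
    nbits <- .read_u64(con)
    rs <- .read_stream_payload(con, rbits, sprintf("read stream of block %d", i))
    ns <- .read_stream_payload(con, nbits, sprintf("N stream of block %d", i))
    blocks[[i]] <- srcomp_block(rc, nc, rs, ns)
  }
  if (length(readBin(con, "raw", n = 1L)))
    stop("corrupt file: trailing bytes after the last block")
  if (nblocks > 0 &&
      sum(vapply(blocks, function(b) b$read_count, numeric(1))) != total)
    stop("corrupt file: block read counts do not sum to the header total")
  structure(list(read_length = read_length, total_read_count = total,
                 block_count = nblocks, blocks = blocks,
                 format_version = version, path = path),
            class = "srcomp_container")
}

.container_payload_bytes <- function(x) {
  sum(vapply(x$blocks, function(b)
    length(b$read_stream$bytes) + length(b$n_stream$bytes), numeric(1)))
}

#' @export
print.srcomp_container <- function(x, ...) {
  cat(sprintf(
    "<srcomp_container v%d> %s reads of length %s in %d block(s), %s payload bytes\n",
    x$format_version, format(x$total_read_count),
    format(x$read_length), x$block_count,
    format(.container_payload_bytes(x))))
  invisible(x)
}
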