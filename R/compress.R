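.encode_block <- function(raw_reads, bucket_capacity) {
  sub <- substitute_ns(raw_reads)
  ord <- sort_order(sub$reads, bucket_capacity)
  sorted <- sub$reads[ord]
  marks <- sub$marks[ord]
  p <- collect_ordinals(sorted, marks)
  q <- if (length(p)) encode_ordinals(p) else numeric(0)
  srcomp_block(length(sorted), length(p),
               cpp_encode_reads(sorted),
               cpp_omega_stream_encode(q))
}

# Sort+encode one chunk, re-splitting by one more leading base when a
# partition still exceeds the usable memory share (prefix skew).
.encode_chunk <- function(raw_reads, depth, read_length, bucket_capacity,
                          usable_bytes) {
  if (length(raw_reads) * read_length > usable_bytes && depth < read_length) {
    keys <- substr(chartr("N", "G", raw_reads), 1L, depth + 1L)
    groups <- split(raw_reads, keys)
    groups <- groups[sort(names(groups), method = "radix")]
    unlist(lapply(groups, .encode_chunk, depth = depth + 1L,
                  read_length = read_length,
                  bucket_capacity = bucket_capacity,
                  usable_bytes = usable_bytes),
           recursive = FALSE, use.names = FALSE)
  } else {
    list(.encode_block(raw_reads, bucket_capacity))
  }
}

.report <- function(container_path, n, L, n_count, block_count) {
  file_bytes <- file.size(container_path)
  cont <- read_container(container_path)
  payload <- .container_payload_bytes(cont)
  list(read_count = n, read_length = L, n_count = n_count,
       block_count = block_count, payload_bytes = payload,
       file_bytes = file_bytes,
       bpb = if (n > 0 && L > 0) 8 * payload / (n * L) else NA_real_)
}

#' Compress an in-memory read collection to a container file
#'
#' The full pipeline: substitute N by G, optionally spill reads to
#' prefix-keyed temporary files, burst-trie sort each partition, collect the
#' G-ordinals of substituted bases, delta+1 transform the packed reads and
#' write omega-coded bitstreams as independent blocks.
#'
#' @param reads Character vector of equal-length reads over A/C/G/T/N
#'   (case-insensitive).
#' @param output Output container path.
#' @param bucket_capacity Burst-trie bucket capacity (default 8192).
#' @param memory_limit Memory budget in bytes used to plan partitioning
#'   (default 1 GiB); see [plan_partitions()].
#' @param prefix_depth Override the planned partition prefix depth (`NULL`
#'   for automatic; 0 forces a single in-memory partition).
#' @param tmp_dir Scratch directory for spill files (default [tempdir()]);
#'   spill files are removed on exit, success or failure.
#' @param verbose Print a one-line report.
#' @return Report list with `read_count`, `read_length`, `n_count`,
#'   `block_count`, `payload_bytes`, `file_bytes` and `bpb` (bits encoded per
#'   base, `8 * payload_bytes / (n * L)`), invisibly.
#' @seealso [decompress_reads()], [srcomp_compress()]
#' @export
compress_reads <- function(reads, output, bucket_capacity = 8192L,
                           memory_limit = 2^30, prefix_depth = NULL,
                           tmp_dir = tempdir(), verbose = FALSE) {
  reads <- .validate_reads(toupper(as.character(reads)))
  n <- length(reads)
  L <- if (n) nchar(reads[1L]) else 0L
  if (n == 0L) {
    write_container(output, list(), 0L, 0)
    rep <- .report(output, 0L, 0L, 0, 0L)
    if (verbose) message("compressed 0 reads (empty container)")
    return(invisible(rep))
  }
  k <- if (is.null(prefix_depth)) {
    plan_partitions(n, L, memory_limit)$prefix_depth
  } else {
    pd <- as.integer(prefix_depth)
    if (pd < 0L || pd > L) stop("prefix_depth must lie in [0, read_length]")
    pd
  }
  usable <- memory_limit * 0.5
  blocks <- if (k == 0L) {
    .encode_chunk(reads, 0L, L, bucket_capacity, usable)
  } else {
    spill_dir <- tempfile("srcomp_spill_", tmpdir = tmp_dir)
    on.exit(unlink(spill_dir, recursive = TRUE), add = TRUE)
    parts <- spill_reads(reads, k, spill_dir)
    out <- list()
    for (i in seq_len(nrow(parts))) {
      chunk <- readLines(parts$path[i])
      out <- c(out, .encode_chunk(chunk, k, L, bucket_capacity, usable))
      unlink(parts$path[i])
    }
    out
  }
  n_count <- sum(vapply(blocks, function(b) b$n_count, numeric(1)))
  write_container(output, blocks, L, n)
  rep <- .report(output, n, L, n_count, length(blocks))
  if (verbose)
    message(sprintf(
      "compressed %d reads (L = %d, %d ambiguous bases) into %d block(s): %.3f bpb",
      n, L, as.integer(n_count), length(blocks), rep$bpb))
  invisible(rep)
}

#' Decompress a container back to its sorted read multiset
#'
#' Each block's read stream is decoded (delta+1 inverted, integers unpacked
#' to bases) and its ordinal stream is used to substitute the recorded G
#' occurrences back to N. Blocks concatenate into the full collection in
#' lexicographic order of the substituted reads; the original file order and
#' read names were not stored and are not recovered.
#'
#' @param input Container path.
#' @return Character vector of reads over A/C/G/T/N.
#' @export
decompress_reads <- function(input) {
  cont <- read_container(input)
  out <- vector("list", cont$block_count)
  for (i in seq_len(cont$block_count)) {
    b <- cont$blocks[[i]]
    reads <- cpp_decode_reads(b$read_stream$bytes, b$read_stream$nbits,
                              b$read_count, cont$read_length)
    q <- cpp_omega_stream_decode(b$n_stream$bytes, b$n_stream$nbits,
                                 b$n_count)
    out[[i]] <- restore_ns(reads, decode_ordinals(q))
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compress a sequence file
#'
#' File-level wrapper around [compress_reads()]: reads FASTQ, FASTA or
#' one-read-per-line text (see [read_sequences()]) and writes an `.srcomp`
#' container.
#'
#' @param input Input sequence file.
#' @param output Output container path.
#' @param format Input format, `"auto"` to detect from the extension.
#' @inheritParams compress_reads
#' @return The compression report, invisibly (see [compress_reads()]).
#' @export
srcomp_compress <- function(input, output,
                            format = c("auto", "fastq", "fasta", "lines"),
                            bucket_capacity = 8192L, memory_limit = 2^30,
                            prefix_depth = NULL, tmp_dir = tempdir(),
                            verbose = FALSE) {
  reads <- read_sequences(input, match.arg(format))
  compress_reads(reads, output, bucket_capacity = bucket_capacity,
                 memory_limit = memory_limit, prefix_depth = prefix_depth,
                 tmp_dir = tmp_dir, verbose = verbose)
}

#' Decompress a container to a sequence file
#'
#' @param input Container path.
#' @param output Output file path.
#' @param format Output format: `"lines"` or `"fasta"`.
#' @param verbose Print a one-line report.
#' @return Report list with `read_count` and `read_length`, invisibly.
#' @export
srcomp_decompress <- function(input, output, format = c("lines", "fasta"),
                              verbose = FALSE) {
  reads <- decompress_reads(input)
  write_sequences(reads, output, match.arg(format))
  if (verbose)
    message(sprintf("decompressed %d reads to %s", length(reads), output))
  invisible(list(read_count = length(reads),
                 read_length = if (length(reads)) nchar(reads[1L]) else 0L))
}

#' Summarize a container without decoding its payload
#'
#' Prints the header fields, a per-block table and the bits-per-base rate
#' computed from the stored stream sizes.
#'
#' @param input Container path.
#' @return List with `read_length`, `read_count`, `n_count`, `block_count`,
#'   `payload_bytes`, `file_bytes`, `bpb` and a per-block data frame
#'   `blocks`, invisibly.
#' @export
srcomp_stats <- function(input) {
  cont <- read_container(input)
  blocks <- data.frame(
    block = seq_len(cont$block_count),
    reads = vapply(cont$blocks, function(b) b$read_count, numeric(1)),
    ambiguous = vapply(cont$blocks, function(b) b$n_count, numeric(1)),
    read_bits = vapply(cont$blocks, function(b) b$read_stream$nbits, numeric(1)),
    n_bits = vapply(cont$blocks, function(b) b$n_stream$nbits, numeric(1)))
  payload <- .container_payload_bytes(cont)
  n <- cont$total_read_count
  L <- cont$read_length
  bpb <- if (n > 0 && L > 0) 8 * payload / (n * L) else NA_real_
  cat(sprintf("srcomp container v%d: %s reads of length %s, %s ambiguous bases, %d block(s)\n",
              cont$format_version, format(n), format(L),
              format(sum(blocks$ambiguous)), cont$block_count))
  cat(sprintf("payload: %s bytes (%s bpb)\n", format(payload),
              if (is.na(bpb)) "n/a" else sprintf("%.3f", bpb)))
  if (nrow(blocks)) print(blocks, row.names = FALSE)
  invisible(list(read_length = L, read_count = n,
                 n_count = sum(blocks$ambiguous),
                 block_count = cont$block_count, payload_bytes = payload,
                 file_bytes = file.size(input), bpb = bpb, blocks = blocks))
}
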