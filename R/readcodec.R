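.BASE4 <- c(A = 0, C = 1, G = 2, T = 3)

.check_acgt <- function(reads, what = "read") {
  bad <- grep("[^ACGT]", reads)
  if (length(bad))
    stop(sprintf("invalid base in %s %d: only A, C, G, T allowed here",
                 what, bad[1L]))
  invisible(reads)
}

#' Map fixed-length reads to their 2-bit packed integer values
#'
#' Each base contributes two bits (A=00, C=01, G=10, T=11), leftmost base most
#' significant, so a read of length L maps to a value in `[0, 4^L - 1]` and
#' numeric order of the values equals lexicographic order of the reads.
#'
#' This R-level helper returns doubles and therefore supports reads up to 26
#' bases (values below 2^53); the compression pipeline itself uses an internal
#' unbounded codec and has no such limit.
#'
#' @param reads Character vector of equal-length A/C/G/T strings.
#' @return Numeric vector of non-negative integer values.
#' @examples
#' read_to_int(c("AAAA", "CGCA", "TTTT"))
#' @seealso [int_to_read()]
#' @export
read_to_int <- function(reads) {
  if (!length(reads)) return(numeric(0))
  L <- nchar(reads[1L])
  if (any(nchar(reads) != L)) stop("reads must all have the same length")
  if (L > 26L)
    stop("read length above 26 exceeds exact double precision; ",
         "the compression pipeline handles long reads internally")
  .check_acgt(reads)
  weights <- 4^((L - 1L):0)
  vapply(strsplit(reads, "", fixed = TRUE),
         function(ch) sum(.BASE4[ch] * weights), numeric(1))
}

#' Recover reads from their packed integer values
#'
#' Inverse of [read_to_int()]: expands each value in base 4 and left-pads with
#' A (digit 0) to the requested read length.
#'
#' @param values Numeric vector of non-negative integers below `4^read_length`.
#' @param read_length Read length L.
#' @return Character vector of reads.
#' @examples
#' int_to_read(100, 4) # "CGCA"
#' @export
int_to_read <- function(values, read_length) {
  read_length <- as.integer(read_length)
  if (read_length < 1L || read_length > 26L)
    stop("read_length must be between 1 and 26 for the double-based codec")
  values <- as.numeric(values)
  if (any(is.na(values) | values < 0 | values != floor(values)))
    stop("values must be non-negative integers")
  if (any(values >= 4^read_length))
    stop("value out of range for read_length ", read_length)
  bases <- c("A", "C", "G", "T")
  out <- character(length(values))
  digits <- matrix("", nrow = length(values), ncol = read_length)
  v <- values
  for (j in read_length:1) {
    digits[, j] <- bases[(v %% 4) + 1]
    v <- v %/% 4
  }
  do.call(paste0, as.data.frame(digits, stringsAsFactors = FALSE))
}

#' Delta+1 transform of a non-decreasing integer sequence
#'
#' Converts the sorted packed-read sequence R into the strictly positive
#' sequence D fed to the omega coder: `d_1 = r_1 + 1` and
#' `d_i = r_i - r_(i-1) + 1`. One is added to every difference because there
#' is no Elias omega code for zero; identical consecutive reads (difference
#' zero) therefore map to the minimal 1-bit codeword.
#'
#' @param sorted_values Non-decreasing numeric vector of non-negative integers.
#' @return Numeric vector of positive deltas, same length as the input.
#' @examples
#' to_deltas(c(0, 5, 5, 9)) # 1 6 1 5
#' @seealso [from_deltas()]
#' @export
to_deltas <- function(sorted_values) {
  sorted_values <- as.numeric(sorted_values)
  if (!length(sorted_values)) return(numeric(0))
  if (any(is.na(sorted_values) | sorted_values < 0 |
          sorted_values != floor(sorted_values)))
    stop("values must be non-negative integers")
  if (any(sorted_values > 2^53)) stop("values above 2^53 are not exact doubles")
  if (is.unsorted(sorted_values))
    stop("input is not non-decreasing; sort the values first")
  c(sorted_values[1L] + 1, diff(sorted_values) + 1)
}

#' Invert the delta+1 transform
#'
#' @param deltas Numeric vector of positive integers.
#' @return Non-decreasing numeric vector with `r_1 = d_1 - 1` and
#'   `r_i = r_(i-1) + d_i - 1`.
#' @examples
#' from_deltas(c(1, 6, 1, 5)) # 0 5 5 9
#' @export
from_deltas <- function(deltas) {
  deltas <- as.numeric(deltas)
  if (!length(deltas)) return(numeric(0))
  if (any(is.na(deltas) | deltas < 1 | deltas != floor(deltas)))
    stop("deltas must be positive integers")
  cumsum(deltas - 1)
}

#' Encode sorted reads as a packed omega-coded byte stream
#'
#' The pipeline composition for one block: pack each read to its 2-bit
#' integer, apply the delta+1 transform and concatenate the omega codewords,
#' byte-padding with zeros only at the end of the stream. Unlike
#' [read_to_int()] this path is unbounded in read length.
#'
#' @param sorted_reads Character vector of equal-length A/C/G/T reads in
#'   lexicographic order.
#' @return A list with `bytes` (raw vector) and `nbits` (exact bit count
#'   before padding).
#' @examples
#' encode_read_stream(c("AAAA", "AAAA")) # two 1-bit codewords
#' @seealso [decode_read_stream()]
#' @export
encode_read_stream <- function(sorted_reads) {
  cpp_encode_reads(as.character(sorted_reads))
}

#' Decode a packed omega-coded byte stream back to sorted reads
#'
#' @param stream A list with `bytes` and `nbits` as produced by
#'   [encode_read_stream()].
#' @param count Number of reads to decode.
#' @param read_length Read length L.
#' @return Character vector of `count` reads in lexicographic order.
#' @export
decode_read_stream <- function(stream, count, read_length) {
  cpp_decode_reads(stream$bytes, as.numeric(stream$nbits),
                   as.numeric(count), as.integer(read_length))
}
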