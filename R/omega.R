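#' Coerce a bit representation to an integer 0/1 vector
#'
#' Accepts either an integer/numeric vector of 0s and 1s or a single string
#' such as `"10100100010"` and returns an integer vector of bits.
#'
#' @param x Bits as a 0/1 vector or a single character string of `0`/`1`.
#' @return Integer vector of 0s and 1s.
#' @examples
#' as_bits("10100100010")
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("supply a single bit string")
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("bits must be 0 or 1")
  x
}

#' Elias omega encoding of a positive integer
#'
#' Builds the self-delimiting omega codeword by the recursive construction:
#' start from a single terminator bit 0; while the value exceeds 1, prefix the
#' bitstream with the binary representation of the value and replace the
#' value by the floor of its base-2 logarithm. Small integers get very short
#' codewords (`omega_encode(1)` is the single bit 0), which is what makes the
#' code efficient on delta-transformed sorted reads.
#'
#' @param n A single positive integer (there is no omega code for zero).
#' @return Integer vector of bits, most significant first.
#' @examples
#' omega_encode(17) # 1 0 1 0 0 1 0 0 0 1 0, 11 bits
#' @seealso [omega_decode()], [encode_sequence()]
#' @export
omega_encode <- function(n) {
  if (length(n) != 1L) stop("n must be a single positive integer")
  cpp_omega_encode_bits(as.numeric(n))
}

#' Elias omega decoding of a single codeword
#'
#' Reads one codeword from the start of the bit vector: a value of 1 grows
#' through the chain of length groups until a 0 bit stops the loop. The
#' number of bits consumed is attached as attribute `"nbits"`, so the caller
#' can continue decoding a concatenated stream.
#'
#' @param bits Bits as accepted by [as_bits()].
#' @return The decoded positive integer (numeric), with attribute `nbits`.
#' @examples
#' omega_decode("10100100010") # 17
#' @export
omega_decode <- function(bits) {
  out <- cpp_omega_decode_bits(as_bits(bits), 1)
  structure(out[[1L]], nbits = attr(out, "nbits"))
}

#' Encode a sequence of positive integers as concatenated omega codewords
#'
#' Codewords are concatenated with no padding in between; because the code is
#' self-delimiting the concatenation is decodable given the element count.
#'
#' @param values Numeric vector of positive integers (each below 2^53).
#' @return Integer vector of bits.
#' @examples
#' encode_sequence(c(2, 17, 1))
#' @seealso [decode_sequence()]
#' @export
encode_sequence <- function(values) {
  cpp_omega_encode_bits(as.numeric(values))
}

#' Decode a fixed number of omega codewords from a bitstream
#'
#' @param bits Bits as accepted by [as_bits()].
#' @param count Number of codewords to decode.
#' @return Numeric vector of `count` positive integers, with attribute
#'   `nbits` giving the bits consumed.
#' @examples
#' decode_sequence(encode_sequence(c(2, 17, 1)), 3)
#' @export
decode_sequence <- function(bits, count) {
  if (length(count) != 1L || is.na(count) || count < 0)
    stop("count must be a single non-negative integer")
  cpp_omega_decode_bits(as_bits(bits), as.numeric(count))
}
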