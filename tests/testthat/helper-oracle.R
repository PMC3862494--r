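# Independent reference implementations used as oracles; deliberately naive
# and separate from the package's code paths.

# Elias omega codeword by the literal recursion on R integers.
ref_omega_encode <- function(n) {
  bits <- 0L
  while (n > 1) {
    b <- integer(0)
    m <- n
    while (m > 0) {
      b <- c(m %% 2L, b)
      m <- m %/% 2L
    }
    bits <- c(b, bits)
    n <- length(b) - 1L
  }
  as.integer(bits)
}

# Packed-read value via per-base 2-bit strings evaluated as one binary number.
ref_read_to_int <- function(read) {
  two_bits <- c(A = "00", C = "01", G = "10", T = "11")
  ch <- strsplit(read, "", fixed = TRUE)[[1L]]
  strtoi(paste(two_bits[ch], collapse = ""), base = 2L)
}

random_reads <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

bit_string <- function(bits) paste(bits, collapse = "")
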