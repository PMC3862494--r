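test_that("an empty collection writes a header-only container", {
  f <- tempfile(fileext = ".srcomp")
  compress_reads(character(0), f)
  cont <- read_container(f)
  expect_equal(cont$block_count, 0)
  expect_equal(cont$total_read_count, 0)
  expect_identical(decompress_reads(f), character(0))
})

test_that("two identical minimal reads decode to deltas [1, 1]", {
  f <- tempfile(fileext = ".srcomp")
  compress_reads(c("AAAA", "AAAA"), f)
  cont <- read_container(f)
  b <- cont$blocks[[1]]
  expect_equal(b$read_stream$nbits, 2) # d1 = 0+1, d2 = 0-0+1: two 1-bit words
  bits <- as_bits(paste(rep("0", 2), collapse = ""))
  expect_equal(as.numeric(decode_sequence(bits, 2)), c(1, 1))
})

test_that("write/read round trip preserves the container structurally", {
  set.seed(51)
  x <- generate_reads(800, 14, n_rate = 0.05, duplication_rate = 0.3)
  f <- tempfile(fileext = ".srcomp")
  rep1 <- compress_reads(x, f, prefix_depth = 1)
  cont <- read_container(f)
  expect_equal(cont$read_length, 14)
  expect_equal(cont$total_read_count, 800)
  expect_equal(sum(vapply(cont$blocks, `[[`, numeric(1), "read_count")), 800)
  f2 <- tempfile(fileext = ".srcomp")
  write_container(f2, cont$blocks, cont$read_length, cont$total_read_count)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f, "raw", file.size(f)))
})

test_that("compression is byte-deterministic", {
  set.seed(52)
  x <- generate_reads(500, 20, n_rate = 0.02, duplication_rate = 0.5)
  f1 <- tempfile(); f2 <- tempfile()
  compress_reads(x, f1)
  compress_reads(x, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # for N-free input even the original read order is irrelevant
  y <- generate_reads(500, 20, n_rate = 0, duplication_rate = 0.5)
  compress_reads(y, f1)
  compress_reads(sample(y), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("bad magic, truncation and version drift are rejected", {
  f <- tempfile()
  writeBin(charToRaw("NOTSRCOMPFILE"), f)
  expect_error(read_container(f), "magic")
  set.seed(53)
  g <- tempfile()
  compress_reads(generate_reads(100, 10, n_rate = 0.05), g)
  bytes <- readBin(g, "raw", file.size(g))
  writeBin(bytes[1:(length(bytes) - 5)], f)
  expect_error(read_container(f), "corrupt|truncat")
  tampered <- bytes
  tampered[7] <- as.raw(99) # version byte
  writeBin(tampered, f)
  expect_error(read_container(f), "version")
})

test_that("payload bit flips never pass silently", {
  set.seed(54)
  x <- generate_reads(300, 12, n_rate = 0.05)
  f <- tempfile()
  compress_reads(x, f)
  bytes <- readBin(f, "raw", file.size(f))
  payload_start <- 8 + 4 + 8 + 4 + 32 + 1
  set.seed(55)
  flips <- sample(payload_start:length(bytes), 20)
  ok_sorted <- sort(x, method = "radix")
  g <- tempfile()
  for (pos in flips) {
    tampered <- bytes
    tampered[pos] <- xor(tampered[pos], as.raw(sample(c(1L, 2L, 64L, 128L), 1)))
    writeBin(tampered, g)
    res <- tryCatch(decompress_reads(g), error = function(e) e)
    silent_ok <- !inherits(res, "error") &&
      identical(sort(res, method = "radix"), ok_sorted)
    expect_false(silent_ok, info = sprintf("flip at byte %d", pos))
  }
})

test_that("payload bits equal the sum of codeword lengths plus padding", {
  set.seed(56)
  x <- sort(random_reads(200, 10), method = "radix")
  f <- tempfile()
  compress_reads(x, f)
  cont <- read_container(f)
  b <- cont$blocks[[1]]
  expected <- length(encode_sequence(to_deltas(read_to_int(x))))
  expect_equal(b$read_stream$nbits, expected)
  expect_lt(length(b$read_stream$bytes) * 8 - b$read_stream$nbits, 8)
})
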