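test_that("2-bit packing matches the positional base-4 expansion", {
  expect_equal(read_to_int("AAAA"), 0)
  expect_equal(read_to_int("TTTT"), 255) # 4^4 - 1
  expect_equal(read_to_int("CGCA"), 100) # oracle: 01 10 01 00 as binary
  expect_equal(read_to_int("CGCA"), ref_read_to_int("CGCA"))
  set.seed(11)
  rds <- random_reads(200, 12)
  expect_equal(read_to_int(rds), vapply(rds, ref_read_to_int, numeric(1),
                                        USE.NAMES = FALSE))
})

test_that("packing rejects bad bases and over-long reads", {
  expect_error(read_to_int("ACGN"), "invalid base")
  expect_error(read_to_int(strrep("A", 27)), "26")
  expect_error(int_to_read(256, 4), "out of range")
})

test_that("int_to_read inverts read_to_int with A left-padding", {
  expect_identical(int_to_read(0, 4), "AAAA")
  expect_identical(int_to_read(100, 4), "CGCA")
  expect_identical(int_to_read(1, 4), "AAAC")
  set.seed(12)
  for (L in c(1L, 5L, 13L, 26L)) {
    rds <- random_reads(500, L)
    expect_identical(int_to_read(read_to_int(rds), L), rds)
  }
})

test_that("packed values are strictly increasing in lexicographic read order", {
  set.seed(13)
  rds <- unique(random_reads(1000, 10))
  by_lex <- sort(rds, method = "radix")
  by_val <- rds[order(read_to_int(rds))]
  expect_identical(by_val, by_lex)
})

test_that("delta+1 transform follows the printed rule and inverts", {
  expect_equal(to_deltas(c(0, 0, 0)), c(1, 1, 1))
  expect_equal(to_deltas(c(0, 5, 5, 9)), c(1, 6, 1, 5))
  expect_equal(from_deltas(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(from_deltas(c(1, 6, 1, 5)), c(0, 5, 5, 9))
  expect_error(to_deltas(c(3, 1)), "non-decreasing")
  expect_error(from_deltas(c(1, 0, 2)), "positive")
  set.seed(14)
  for (i in 1:50) {
    r <- sort(sample.int(1e6, 40, replace = TRUE)) - 1
    d <- to_deltas(r)
    expect_length(d, length(r))
    expect_true(all(d >= 1))
    expect_equal(from_deltas(d), r)
    # conservation of the total span
    expect_equal(sum(d - 1), r[length(r)] - r[1] + (d[1] - 1))
  }
})

test_that("identical consecutive reads yield delta 1 and a 1-bit codeword", {
  r <- read_to_int(c("CGCA", "CGCA", "CGCA"))
  d <- to_deltas(r)
  expect_equal(d[2:3], c(1, 1))
  expect_length(omega_encode(d[2]), 1L)
})

test_that("read stream codec agrees with the double-based composition", {
  set.seed(15)
  for (L in c(4L, 13L, 26L)) {
    sorted <- sort(random_reads(300, L), method = "radix")
    st <- encode_read_stream(sorted)
    # independent route: pack -> delta -> omega on doubles
    bits <- encode_sequence(to_deltas(read_to_int(sorted)))
    expect_equal(st$nbits, length(bits))
    expect_identical(decode_read_stream(st, length(sorted), L), sorted)
  }
})

test_that("read stream codec handles reads far beyond double precision", {
  set.seed(16)
  for (L in c(36L, 76L, 150L)) {
    sorted <- sort(random_reads(200, L), method = "radix")
    st <- encode_read_stream(sorted)
    expect_identical(decode_read_stream(st, 200, L), sorted)
  }
})

test_that("encoding unsorted reads is refused", {
  expect_error(encode_read_stream(c("TTTT", "AAAA")), "sorted")
})
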