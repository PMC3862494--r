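write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTQ records yield their sequence lines only", {
  f <- write_tmp(c("@r1 lane1", "ACGTACGT", "+", "IIIIIIII",
                   "@r2", "ggggnnnn", "+", "########"), ".fastq")
  expect_identical(read_sequences(f), c("ACGTACGT", "GGGGNNNN"))
})

test_that("wrapped FASTA records are concatenated per record", {
  f <- write_tmp(c(">chr_a desc", "ACGT", "ACGT", ">chr_b", "TTTTTTTT"),
                 ".fasta")
  expect_identical(read_sequences(f), c("ACGTACGT", "TTTTTTTT"))
})

test_that("lines format ignores trailing blank lines and uppercases", {
  f <- write_tmp(c("acgt", "ACGN", "", ""), ".txt")
  expect_identical(read_sequences(f), c("ACGT", "ACGN"))
  g <- write_tmp(c("ACGT", "", "ACGT"), ".txt")
  expect_error(read_sequences(g), "line 2")
})

test_that("gzip-compressed line input is read transparently", {
  f <- tempfile(fileext = ".txt.gz")
  con <- gzfile(f, "wt")
  writeLines(c("ACGT", "TTTT"), con)
  close(con)
  expect_identical(read_sequences(f), c("ACGT", "TTTT"))
})

test_that("length deviations and foreign alphabets are refused with context", {
  f <- write_tmp(c("ACGT", "ACGTA"), ".txt")
  expect_error(read_sequences(f), "read 2 has length 5")
  g <- write_tmp(c(">a", "ACRT"), ".fa")
  expect_error(read_sequences(g), "outside A/C/G/T/N")
})

test_that("format is detected from the extension and can be overridden", {
  f <- write_tmp(c(">a", "ACGT"), ".fa")
  expect_identical(read_sequences(f), "ACGT")
  g <- write_tmp(c("AAAA", "CCCC"), ".dat")
  expect_identical(read_sequences(g, format = "lines"), c("AAAA", "CCCC"))
})

test_that("writers round trip through both output formats", {
  f <- tempfile(fileext = ".txt")
  expect_equal(write_sequences(character(0), f), 0)
  expect_identical(readLines(f), character(0))
  rds <- c("ACGT", "NNNN", "TTTT")
  write_sequences(rds, f)
  expect_identical(readLines(f), rds)
  g <- tempfile(fileext = ".fa")
  write_sequences(rds, g, format = "fasta")
  expect_identical(read_sequences(g), rds)
  expect_identical(readLines(g)[1], ">read_1")
})

test_that("the generator is deterministic per seed and hits its rates", {
  a <- generate_reads(200, 30, n_rate = 0.01, duplication_rate = 0.4, seed = 9)
  b <- generate_reads(200, 30, n_rate = 0.01, duplication_rate = 0.4, seed = 9)
  expect_identical(a, b)
  expect_identical(generate_reads(0, 30), character(0))
  # N rate within 5 binomial standard deviations
  x <- generate_reads(1e5, 36, n_rate = 0.01, seed = 10)
  n_obs <- sum(nchar(x)) - sum(nchar(gsub("N", "", x, fixed = TRUE)))
  expected <- 0.01 * 1e5 * 36
  expect_lt(abs(n_obs - expected), 5 * sqrt(expected * 0.99))
  # duplication: at most n * (1 - duplication_rate) distinct reads
  y <- generate_reads(5000, 36, n_rate = 0, duplication_rate = 0.5, seed = 11)
  expect_lte(length(unique(y)), 2500)
})

test_that("coverage-mode reads are windows of one backing sequence", {
  x <- generate_reads(3000, 25, n_rate = 0, genome_length = 500, seed = 12)
  expect_lte(length(unique(x)), 476) # at most genome_length - L + 1 windows
  expect_error(generate_reads(10, 50, genome_length = 30), "at least")
})
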