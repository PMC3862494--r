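test_that("the smallest sufficient prefix depth is chosen", {
  # everything fits: single in-memory partition
  expect_equal(plan_partitions(1000, 36, 2^30)$prefix_depth, 0L)
  # 4e6 * 36 bytes against a budget forcing a 4-way split
  expect_equal(plan_partitions(4e6, 36, 1.5e8)$prefix_depth, 1L)
  expect_equal(plan_partitions(4e6, 36, 3e7)$prefix_depth, 2L)
  expect_error(plan_partitions(1e9, 2, 4), "infeasible")
})

test_that("prefix depth never exceeds the read length", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample.int(1e7, 1)
    L <- sample.int(100, 1)
    budget <- 10^stats::runif(1, 3, 9)
    k <- tryCatch(plan_partitions(n, L, budget)$prefix_depth,
                  error = function(e) NA_integer_)
    if (!is.na(k)) {
      expect_lte(k, L)
      expect_lte(n * L / 4^k, 0.5 * budget)
      if (k > 0) expect_gt(n * L / 4^(k - 1), 0.5 * budget)
    }
  }
})

test_that("spilling keys reads on their first bases, N counting as G", {
  dir <- tempfile("spill")
  parts <- spill_reads(c("CGCA", "AAAA", "TTTT", "CAAG"), 1, dir)
  expect_identical(parts$key, c("A", "C", "T"))
  expect_identical(readLines(parts$path[parts$key == "C"]), c("CGCA", "CAAG"))
  expect_identical(readLines(parts$path[parts$key == "A"]), "AAAA")
  # a read starting with N lands in the G partition
  parts2 <- spill_reads(c("NAAA", "GAAA"), 1, tempfile("spill"))
  expect_identical(parts2$key, "G")
  expect_equal(sum(parts2$count), 2)
  unlink(dir, recursive = TRUE)
})

test_that("partition counts conserve the input", {
  set.seed(42)
  x <- generate_reads(3000, 12, n_rate = 0.02)
  dir <- tempfile("spill")
  parts <- spill_reads(x, 2, dir)
  expect_equal(sum(parts$count), length(x))
  back <- unlist(lapply(parts$path, readLines), use.names = FALSE)
  expect_identical(sort(back, method = "radix"), sort(x, method = "radix"))
  unlink(dir, recursive = TRUE)
})

test_that("partitioned and in-memory compression produce equivalent output", {
  set.seed(43)
  x <- generate_reads(4000, 24, n_rate = 0.05, duplication_rate = 0.2,
                      genome_length = 8000)
  f0 <- tempfile(fileext = ".srcomp")
  f1 <- tempfile(fileext = ".srcomp")
  compress_reads(x, f0, prefix_depth = 0)
  compress_reads(x, f1, prefix_depth = 1)
  expect_identical(decompress_reads(f0), decompress_reads(f1))
  expect_gt(read_container(f1)$block_count, 1)
})

test_that("per-block sorted reads concatenate into a globally sorted stream", {
  set.seed(44)
  x <- generate_reads(3000, 16, n_rate = 0.03)
  f <- tempfile(fileext = ".srcomp")
  compress_reads(x, f, prefix_depth = 2)
  out <- chartr("N", "G", decompress_reads(f))
  expect_false(is.unsorted(out))
})

test_that("a skewed partition re-splits on a deeper prefix by itself", {
  # all reads share the first base, so the k=1 partition holds everything
  # and must be split again to honor the budget
  set.seed(45)
  x <- paste0("A", generate_reads(512, 11, n_rate = 0))
  f <- tempfile(fileext = ".srcomp")
  compress_reads(x, f, prefix_depth = 1, memory_limit = 4096)
  cont <- read_container(f)
  expect_gt(cont$block_count, 1)
  expect_identical(sort(decompress_reads(f), method = "radix"),
                   sort(x, method = "radix"))
})
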