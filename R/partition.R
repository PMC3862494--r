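#' Plan external-memory prefix partitioning
#'
#' When a read collection is too large to sort in memory, reads are first
#' distributed to temporary files keyed by their first k bases (as in an MSD
#' radix pass) and each file is then sorted and encoded independently in
#' lexicographic key order. This chooses the smallest prefix depth k such
#' that the expected partition size `n * L / 4^k` fits in the usable share of
#' the memory budget (`memory_budget * fill_factor`; the fill factor absorbs
#' trie overhead on top of the raw read bytes).
#'
#' @param read_count Number of reads n.
#' @param read_length Read length L in bases.
#' @param memory_budget Target bytes available per partition.
#' @param fill_factor Fraction of the budget counted as usable (default 0.5).
#' @return Object of class `partition_plan`: a list with `prefix_depth`,
#'   `read_count`, `read_length`, `memory_budget`, `fill_factor` and
#'   `expected_partition_bytes`.
#' @examples
#' plan_partitions(4e6, 36, 1.5e8) # forces a 4-way split: k = 1
#' @export
plan_partitions <- function(read_count, read_length, memory_budget,
                            fill_factor = 0.5) {
  if (read_count < 0 || read_length < 1 || memory_budget <= 0 ||
      fill_factor <= 0 || fill_factor > 1)
    stop("invalid partition planning arguments")
  usable <- memory_budget * fill_factor
  bytes <- read_count * read_length
  k <- 0L
  while (bytes / 4^k > usable && k < read_length) k <- k + 1L
  if (bytes / 4^k > usable)
    stop(sprintf(
      "infeasible memory budget: even %d-base prefixes leave expected partitions of %.0f bytes",
      as.integer(read_length), bytes / 4^k))
  structure(list(prefix_depth = k, read_count = read_count,
                 read_length = read_length, memory_budget = memory_budget,
                 fill_factor = fill_factor,
                 expected_partition_bytes = bytes / 4^k),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf(
    "<partition_plan> prefix depth %d (up to %d partitions), ~%.0f bytes each for %s reads of length %d\n",
    x$prefix_depth, 4L^x$prefix_depth, x$expected_partition_bytes,
    format(x$read_count, big.mark = ","), x$read_length))
  invisible(x)
}

#' Spill reads into prefix-keyed temporary files
#'
#' Each read is appended to the file of its length-k prefix; the key is taken
#' on the N-substituted read (N counts as G) so a read starting with N lands
#' in the G partition and the per-partition blocks concatenate into a
#' globally sorted collection. The spilled lines keep their Ns: substitution
#' marks are recomputed per partition when it is loaded back.
#'
#' @param reads Character vector over A/C/G/T/N (uppercase).
#' @param prefix_depth Number of leading bases used as the partition key.
#' @param dir Directory for the spill files (created if needed).
#' @return Data frame with one row per non-empty partition: `key`, `path`,
#'   `count`, ordered lexicographically by key.
#' @export
spill_reads <- function(reads, prefix_depth, dir) {
  prefix_depth <- as.integer(prefix_depth)
  if (prefix_depth < 1L) stop("prefix_depth must be >= 1 for spilling")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keys <- substr(chartr("N", "G", reads), 1L, prefix_depth)
  groups <- split(reads, keys)
  groups <- groups[sort(names(groups), method = "radix")]
  paths <- file.path(dir, paste0("part_", names(groups), ".txt"))
  for (i in seq_along(groups)) {
    ok <- tryCatch({ writeLines(groups[[i]], paths[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("I/O error spilling partition '%s': %s",
                   names(groups)[i], conditionMessage(ok)))
  }
  data.frame(key = names(groups), path = paths,
             count = lengths(groups), row.names = NULL,
             stringsAsFactors = FALSE)
}
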