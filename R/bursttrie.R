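#' Create an empty burst trie
#'
#' A burst trie is a trie whose sufficiently small subtrees are represented as
#' bounded-capacity buckets (growable arrays of read references). Reads are
#' inserted one after another, inspecting one base per level until they can be
#' assigned to a bucket; a bucket pushed past its capacity bursts into a new
#' trie node one level deeper. Because all reads share one length L, a bucket
#' at depth L holds only identical reads and is exempt from bursting.
#'
#' @param capacity Maximum number of entries a bucket may hold before it
#'   bursts (default 8192).
#' @return An object of class `burst_trie`.
#' @examples
#' tr <- burst_trie(capacity = 3)
#' trie_insert(tr, c("CGCA", "CAAG", "TGCT"))
#' trie_stats(tr)
#' @seealso [trie_insert()], [trie_sorted()], [sort_reads()]
#' @export
burst_trie <- function(capacity = 8192L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 2L)
    stop("bucket capacity must be at least 2")
  structure(list(ptr = cpp_bt_new(capacity), capacity = capacity),
            class = "burst_trie")
}

#' Insert reads into a burst trie
#'
#' Reads must be A/C/G/T only (substitute ambiguous bases first, see
#' [substitute_ns()]) and share one length, fixed by the first insertion.
#'
#' @param trie A [burst_trie()].
#' @param reads Character vector of reads.
#' @return The trie, invisibly (the underlying structure is updated in place).
#' @export
trie_insert <- function(trie, reads) {
  stopifnot(inherits(trie, "burst_trie"))
  cpp_bt_insert(trie$ptr, as.character(reads))
  invisible(trie)
}

#' Burst-trie accounting
#'
#' @param trie A [burst_trie()].
#' @return List with `read_count`, `read_length`, `capacity`, `trie_nodes`
#'   (including the root), `buckets` (non-empty buckets only; empty buckets
#'   are never materialized) and `bursts`.
#' @export
trie_stats <- function(trie) {
  stopifnot(inherits(trie, "burst_trie"))
  cpp_bt_stats(trie$ptr)
}

#' Inspect the shape of a burst trie
#'
#' @param trie A [burst_trie()].
#' @return Nested list: nodes carry `depth` and a named `children` list keyed
#'   by base; buckets carry `depth` and their entries in insertion order.
#' @export
trie_structure <- function(trie) {
  stopifnot(inherits(trie, "burst_trie"))
  cpp_bt_structure(trie$ptr)
}

#' Reads in lexicographic order via in-order traversal
#'
#' Traverses the trie depth-first, left to right (A, C, G, T) in each node;
#' within each bucket, entries are stably sorted by a comparison that starts
#' at the base position after the bucket's shared prefix. The result is a
#' stable lexicographic sort of everything inserted.
#'
#' @param trie A [burst_trie()].
#' @return Character vector of reads in sorted order.
#' @export
trie_sorted <- function(trie) {
  stopifnot(inherits(trie, "burst_trie"))
  cpp_bt_sorted(trie$ptr)
}

#' Permutation that sorts the inserted reads
#'
#' @param trie A [burst_trie()].
#' @return Integer permutation `p` such that `reads[p]` is sorted, where
#'   `reads` is the concatenation of everything inserted, in insertion order.
#' @export
trie_order <- function(trie) {
  stopifnot(inherits(trie, "burst_trie"))
  cpp_bt_order(trie$ptr)
}

#' @export
print.burst_trie <- function(x, ...) {
  st <- trie_stats(x)
  cat(sprintf(
    "<burst_trie> %s reads (L = %s), capacity %d: %s nodes, %s buckets, %s bursts\n",
    format(st$read_count), format(st$read_length), st$capacity,
    format(st$trie_nodes), format(st$buckets), format(st$bursts)))
  invisible(x)
}

#' Sort reads lexicographically with a burst trie
#'
#' Convenience composition of trie construction, insertion and in-order
#' traversal. Output order is A < C < G < T, identical to numeric order of
#' the reads' 2-bit packed integers; duplicates are preserved and the sort is
#' stable.
#'
#' @param reads Character vector of equal-length A/C/G/T reads.
#' @param capacity Bucket capacity (default 8192).
#' @return Character vector of the same reads in sorted order.
#' @examples
#' sort_reads(c("TGCT", "CAAG", "CGCA"))
#' @export
sort_reads <- function(reads, capacity = 8192L) {
  tr <- burst_trie(capacity)
  trie_insert(tr, reads)
  trie_sorted(tr)
}

#' @rdname sort_reads
#' @return `sort_order()`: the integer permutation sorting `reads`.
#' @export
sort_order <- function(reads, capacity = 8192L) {
  tr <- burst_trie(capacity)
  trie_insert(tr, reads)
  trie_order(tr)
}
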