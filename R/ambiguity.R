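#' Substitute ambiguous bases (N) by G before sorting
#'
#' Every N becomes a G so the sorter and codec see a pure A/C/G/T alphabet;
#' the positions of the substituted bases are kept per read so they follow
#' the reads through pointer-based sorting and can be restored exactly on
#' decompression. The substitution target is the fixed base G for every N:
#' decompression must know the target deterministically. IUPAC codes other
#' than N (R, Y, ...) are rejected rather than coerced, since coercing them
#' would be lossy.
#'
#' @param raw_reads Character vector over A/C/G/T/N (case-insensitive).
#' @return List with `reads` (substituted, uppercase) and `marks` (a list of
#'   integer position vectors, one per read, of the originally ambiguous
#'   positions).
#' @examples
#' substitute_ns(c("ANGN", "ACGT"))
#' @seealso [collect_ordinals()], [restore_ns()]
#' @export
substitute_ns <- function(raw_reads) {
  reads <- toupper(as.character(raw_reads))
  bad <- grep("[^ACGTN]", reads)
  if (length(bad))
    stop(sprintf(
      "invalid base in read %d: only A, C, G, T, N are supported", bad[1L]))
  m <- gregexpr("N", reads, fixed = TRUE)
  marks <- lapply(m, function(x) if (x[1L] == -1L) integer(0) else as.integer(x))
  list(reads = gsub("N", "G", reads, fixed = TRUE), marks = marks)
}

.g_counts <- function(reads) {
  nchar(reads) - nchar(gsub("G", "", reads, fixed = TRUE))
}

#' Collect G-ordinals of substituted bases across sorted reads
#'
#' Walks the sorted collection left to right, read by read, numbering every
#' occurrence of G from 1, and records the ordinal of each marked (originally
#' N) position. The result P is strictly increasing: the p-th G within the
#' collection of sorted reads originally came from an N.
#'
#' @param sorted_reads Character vector of substituted reads in final sorted
#'   order.
#' @param marks List of integer position vectors parallel to `sorted_reads`
#'   (permute the output of [substitute_ns()] with the sort order).
#' @return Strictly increasing numeric vector of 1-based G-ordinals.
#' @examples
#' collect_ordinals(c("AGGG", "GGAA"), list(c(3L, 4L), integer(0))) # 2 3
#' @export
collect_ordinals <- function(sorted_reads, marks) {
  if (length(sorted_reads) != length(marks))
    stop("marks must be parallel to sorted_reads")
  gcount <- .g_counts(sorted_reads)
  offs <- cumsum(c(0, gcount))
  hit <- which(lengths(marks) > 0L)
  if (!length(hit)) return(numeric(0))
  out <- vector("list", length(hit))
  for (j in seq_along(hit)) {
    i <- hit[j]
    ch <- strsplit(sorted_reads[i], "", fixed = TRUE)[[1L]]
    isg <- ch == "G"
    pos <- marks[[i]]
    if (any(pos < 1L) || any(pos > length(ch)) || !all(isg[pos]))
      stop(sprintf(
        "internal consistency error: mark on a non-G position in read %d", i))
    out[[j]] <- offs[i] + cumsum(isg)[pos]
  }
  p <- as.numeric(unlist(out))
  if (is.unsorted(p, strictly = TRUE))
    stop("internal consistency error: ordinals are not strictly increasing")
  p
}

#' Difference-encode a strictly increasing ordinal sequence
#'
#' Converts P into Q with `q_1 = p_1` and `q_j = p_j - p_(j-1)`. Because P is
#' strictly increasing the differences are already positive, so no +1 is
#' needed (unlike the possibly-tied packed-read sequence).
#'
#' @param ordinals Strictly increasing numeric vector of positive integers.
#' @return Numeric vector Q of positive integers.
#' @examples
#' encode_ordinals(c(2, 3)) # 2 1
#' @seealso [decode_ordinals()]
#' @export
encode_ordinals <- function(ordinals) {
  ordinals <- as.numeric(ordinals)
  if (!length(ordinals)) return(numeric(0))
  if (any(is.na(ordinals) | ordinals < 1 | ordinals != floor(ordinals)))
    stop("ordinals must be positive integers")
  if (is.unsorted(ordinals, strictly = TRUE))
    stop("ordinals must be strictly increasing")
  c(ordinals[1L], diff(ordinals))
}

#' Invert the ordinal difference encoding
#'
#' @param q Numeric vector of positive integers.
#' @return Strictly increasing numeric vector `cumsum(q)`.
#' @export
decode_ordinals <- function(q) {
  q <- as.numeric(q)
  if (!length(q)) return(numeric(0))
  if (any(is.na(q) | q < 1 | q != floor(q)))
    stop("encoded ordinal gaps must be positive integers")
  cumsum(q)
}

#' Restore ambiguous bases into a sorted, substituted read collection
#'
#' The p-th G (numbering all Gs across the sorted reads from 1) is replaced
#' by N for every ordinal p; all other bases are untouched.
#'
#' @param sorted_reads Character vector of A/C/G/T reads in sorted order.
#' @param ordinals Strictly increasing numeric vector of G-ordinals.
#' @return Character vector over A/C/G/T/N.
#' @examples
#' restore_ns(c("AGGG", "GGAA"), c(2, 3)) # "AGNN" "GGAA"
#' @export
restore_ns <- function(sorted_reads, ordinals) {
  ordinals <- as.numeric(ordinals)
  if (!length(ordinals)) return(sorted_reads)
  if (any(is.na(ordinals) | ordinals < 1 | ordinals != floor(ordinals)) ||
      is.unsorted(ordinals, strictly = TRUE))
    stop("corrupt stream: ordinals must be strictly increasing positive integers")
  gcount <- .g_counts(sorted_reads)
  cum <- cumsum(gcount)
  total <- if (length(cum)) cum[length(cum)] else 0
  if (ordinals[length(ordinals)] > total)
    stop("corrupt stream: ordinal exceeds the total number of G bases")
  ri <- findInterval(ordinals - 1, cum) + 1L
  local <- ordinals - c(0, cum)[ri]
  out <- sorted_reads
  for (i in unique(ri)) {
    ch <- strsplit(out[i], "", fixed = TRUE)[[1L]]
    gpos <- which(ch == "G")
    ch[gpos[local[ri == i]]] <- "N"
    out[i] <- paste(ch, collapse = "")
  }
  out
}
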