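.detect_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  ext <- tools::file_ext(p)
  if (ext %in% c("fastq", "fq")) "fastq"
  else if (ext %in% c("fasta", "fa", "fna", "ffn")) "fasta"
  else "lines"
}

.validate_reads <- function(reads, source = "input") {
  if (!length(reads)) return(character(0))
  L <- nchar(reads[1L])
  bad <- which(nchar(reads) != L)
  if (length(bad))
    stop(sprintf(
      "%s read %d has length %d but the first read has length %d; variable-length reads are not supported",
      source, bad[1L], nchar(reads[bad[1L]]), L))
  badc <- grep("[^ACGTN]", reads)
  if (length(badc))
    stop(sprintf("%s read %d contains a base outside A/C/G/T/N", source, badc[1L]))
  reads
}

#' Read sequences from FASTQ, FASTA or one-read-per-line text
#'
#' Only the sequence strings are returned: FASTQ quality lines and all read
#' names/headers are discarded, since the compressor stores read sequences
#' alone. Lowercase bases are uppercased; every read must have the same
#' length and use only A/C/G/T/N. Gzip-compressed files are read
#' transparently.
#'
#' @param path Input file path.
#' @param format One of `"auto"` (detect from the extension), `"fastq"`,
#'   `"fasta"`, `"lines"`.
#' @return Character vector of uppercase reads.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta", "lines")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- .detect_format(path)
  reads <- if (format == "lines") {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    x <- sub("\r$", "", readLines(con))
    while (length(x) && x[length(x)] == "") x <- x[-length(x)]
    blank <- which(x == "")
    if (length(blank))
      stop(sprintf("parse error at line %d: blank line inside read list", blank[1L]))
    toupper(x)
  } else {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = format),
      error = function(e)
        stop(sprintf("parse error reading %s as %s: %s",
                     path, format, conditionMessage(e)), call. = FALSE))
    unname(as.character(set))
  }
  .validate_reads(reads, source = basename(path))
}

#' Write sequences as one-read-per-line text or FASTA
#'
#' Original read names are not stored in the container, so FASTA output
#' invents sequential headers `read_1`, `read_2`, ...
#'
#' @param reads Character vector of reads.
#' @param path Output file path.
#' @param format `"lines"` or `"fasta"`.
#' @return Number of records written, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("lines", "fasta")) {
  format <- match.arg(format)
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(reads)) {
    if (format == "lines") {
      writeLines(reads, con)
    } else {
      writeLines(paste0(">read_", seq_along(reads), "\n", reads), con)
    }
  }
  invisible(length(reads))
}

#' Generate a synthetic fixed-length read set
#'
#' Emulates the redundancy structure short-read compression exploits. In
#' coverage mode (`genome_length` set) reads are drawn as windows of one
#' random backing sequence, reproducing the constrained read space of
#' high-coverage sequencing; otherwise reads are uniform random. A fraction
#' `duplication_rate` of the reads are exact copies of other generated reads
#' (mimicking PCR duplicates and highly expressed loci), and each base is
#' independently replaced by N with probability `n_rate` (uncalled bases).
#' Defaults mirror typical short-read data: 36 bp reads with about 1 percent
#' ambiguous bases.
#'
#' @param n Number of reads.
#' @param read_length Read length L (default 36).
#' @param n_rate Per-base probability of an N (default 0.01).
#' @param duplication_rate Fraction of reads that are copies of other reads
#'   (default 0).
#' @param genome_length Optional backing sequence length for coverage-style
#'   sampling; must be at least `read_length`.
#' @param seed Optional RNG seed for reproducible generation; the caller's
#'   RNG state is left untouched when a seed is given.
#' @return Character vector of `n` reads over A/C/G/T/N.
#' @examples
#' generate_reads(5, read_length = 10, n_rate = 0, seed = 1)
#' @export
generate_reads <- function(n, read_length = 36L, n_rate = 0.01,
                           duplication_rate = 0, genome_length = NULL,
                           seed = NULL) {
  n <- as.integer(n)
  read_length <- as.integer(read_length)
  if (n < 0L || read_length < 1L) stop("invalid n or read_length")
  if (n_rate < 0 || n_rate > 1 || duplication_rate < 0 || duplication_rate > 1)
    stop("n_rate and duplication_rate must lie in [0, 1]")
  if (!is.null(genome_length) && genome_length < read_length)
    stop("genome_length must be at least read_length")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  if (n == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  n_fresh <- max(1L, n - as.integer(round(n * duplication_rate)))
  fresh <- if (!is.null(genome_length)) {
    genome <- paste(sample(bases, genome_length, replace = TRUE), collapse = "")
    starts <- sample.int(genome_length - read_length + 1L, n_fresh,
                         replace = TRUE)
    substring(genome, starts, starts + read_length - 1L)
  } else {
    m <- matrix(sample(bases, n_fresh * read_length, replace = TRUE),
                nrow = n_fresh)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  reads <- if (n_fresh < n)
    sample(c(fresh, fresh[sample.int(n_fresh, n - n_fresh, replace = TRUE)]))
  else fresh
  if (n_rate > 0) {
    ch <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                 nrow = read_length)
    mask <- matrix(stats::runif(n * read_length) < n_rate, nrow = read_length)
    ch[mask] <- "N"
    reads <- do.call(paste0, as.data.frame(t(ch), stringsAsFactors = FALSE))
  }
  reads
}
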