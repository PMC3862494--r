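Package: srcomp
Title: Fast Lossless Compression of Fixed-Length Short Sequencing Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-free lossless compressor for collections of
    equal-length DNA short reads. Reads are sorted lexicographically with a
    cache-conscious burst trie, packed two bits per base into a
    non-decreasing integer sequence, delta-transformed and emitted as Elias
    omega codewords; ambiguous bases (N) are substituted by G before sorting
    and restored on decompression from a separately coded ordinal stream.
    Includes FASTQ/FASTA/plain-text readers, an external-memory prefix
    partitioner for collections larger than memory, a deterministic binary
    container format, a synthetic read-set generator and a command-line
    interface. Decompression reproduces the input read multiset exactly;
    read order and names are not preserved.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
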