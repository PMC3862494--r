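---
title: "Sorting-based lossless compression of short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting-based lossless compression of short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcomp)
```

## The model

`srcomp` compresses a collection of *n* equal-length DNA reads by turning it
into a monotone integer sequence and coding the increments. The key
observation is statistical: high-throughput sequencing samples an enormous
number of reads from a comparatively constrained read space (short reads,
high coverage, PCR duplicates), so after lexicographic sorting, consecutive
reads are close — frequently identical. The pipeline is:

1. **Ambiguity substitution.** Every `N` becomes `G` (a fixed, deterministic
   target, so decompression knows it), and the position of each substituted
   base is marked on its read.
2. **Burst-trie sort.** Reads are inserted one after another into a burst
   trie; each read is inspected base by base only until it can be assigned
   to a bucket (a growable array of read references, all sharing the prefix
   spelled by the path to it). A bucket pushed past its capacity *bursts*
   into a trie node one level deeper, redistributing its entries by their
   next base. An in-order traversal (A, C, G, T at every node, buckets
   sorted by a comparison that skips the shared prefix) emits the reads in
   lexicographic order. Only pointers move; the read bytes stay in place.
3. **Packing.** Each read maps to a 2-bit-per-base integer
   (A=00, C=01, G=10, T=11, leftmost base most significant). Numeric order
   of the packed values coincides with lexicographic order of the reads, so
   the sorted collection gives a non-decreasing sequence
   $R = r_1 \le r_2 \le \dots \le r_n$, $0 \le r_i \le 4^L - 1$.
4. **Delta+1.** $d_1 = r_1 + 1$ and $d_i = r_i - r_{i-1} + 1$. Every $d_i$
   is a positive integer — necessary because the Elias omega code has no
   codeword for zero. The transform is invertible without side information.
5. **Elias omega coding.** Each $d_i$ becomes a self-delimiting codeword:
   start from a terminator bit 0 and, while the value exceeds 1, prefix the
   bitstream with the binary representation of the value and replace the
   value by $\lfloor \log_2 \cdot \rfloor$ of itself. The code spends
   1 bit on the value 1 (an exact duplicate read), 11 bits on 17, and grows
   only slightly faster than the information content for large values —
   well matched to a delta distribution skewed towards small integers.

For the ambiguous bases, the sorted collection's G occurrences are numbered
from 1 left to right, read by read; the ordinals $P = p_1 < \dots < p_m$ of
the marked (originally N) Gs are difference-coded
($q_1 = p_1$, $q_j = p_j - p_{j-1}$; strict increase makes every $q_j$
positive without a +1) and omega-coded into a second stream. Decompression
decodes the sorted reads, then turns the $p$-th G back into N.

```{r example}
omega_encode(17)
to_deltas(read_to_int(sort_reads(c("CGCA", "CGCA", "CAAG"))))
```

## What is, and is not, preserved

Decompression reproduces the input **multiset** exactly — every read, every
N in place, every duplicate with its multiplicity. The original read order,
read names and quality scores are not stored; that is the premise of the
method, not a defect. Accordingly the R-level API returns reads in sorted
order, and FASTA output invents sequential headers.

## Tunable parameters

* `bucket_capacity` (default **8192** entries): the trie bursts a bucket
  that exceeds this size. The default follows standard burst-trie practice
  for string sorting; smaller values deepen the trie, larger values push
  more work into the in-bucket sort. Correctness is independent of the
  setting (the tests sweep 2, 3 and 8192).
* `memory_limit` (default **1 GiB**) and `fill_factor` (**0.5**): the
  partition planner picks the smallest prefix depth $k$ with expected
  partition size $nL/4^k \le$ `memory_limit * fill_factor`. The factor 0.5
  is this package's allowance for trie and pointer overhead on top of the
  raw read bytes; no principled formula exists, and any conservative
  constant only changes *when* spilling starts, not the output.
* `prefix_depth`: overrides the planner (0 forces in-memory). Partitions
  are keyed on post-substitution bases, so a read starting with N lands in
  the G partition and blocks concatenate into a globally sorted stream.
  Each block restarts the delta baseline ($d_1 = r_1 + 1$) and numbers its
  G-ordinals locally — blocks are fully independent, which is also what
  makes parallel and streaming decompression possible. A partition that is
  still over budget (heavily skewed prefixes) is re-split one base deeper
  on its own.

## Numerical and format choices

* **Bit order** is most-significant-bit-first; the first appended bit is the
  high bit of the first byte, matching the left-to-right reading of
  codewords. Streams are zero-padded to a byte boundary only at block ends;
  the decoder stops on stored counts, never on padding.
* **Unbounded integers.** A read of length $L$ packs to a $2L$-bit value
  (a 76-mer is a 152-bit integer), so the compiled codec works on 64-bit
  limb vectors with no length limit. The R-level helpers
  (`read_to_int()`, `to_deltas()`, …) return doubles and therefore refuse
  inputs beyond $2^{53}$ (reads longer than 26 bases); they exist for
  inspection, teaching and cross-checking, not as the pipeline.
* **First element convention.** The transform stores $r_1$ as $d_1 = r_1+1$,
  so the all-A read still yields a positive, encodable integer and no
  separate baseline field is needed; the container's format version pins
  this convention.
* **Stability.** The in-bucket sort is stable and keyed on suffixes after
  the shared prefix, so the overall sort is a stable lexicographic sort of
  the insertion order — this makes the trie's output, and hence the whole
  archive, deterministic. For N-free input even the input order is
  irrelevant to the output bytes; with Ns, equal substituted reads carry
  their N-marks in input order (the decompressed multiset is unaffected).
* **Container.** A fixed header (magic `SRCOMP`, version, read length,
  total count, block count) followed by per-block counts, exact bit counts
  and the two byte-aligned streams, all little-endian. Reading validates
  magic, version, count consistency, stream lengths, zero padding and
  absence of trailing bytes; payload corruption is caught by the decoders
  (codeword overruns, range violations, unread trailing bits) or surfaces
  as a multiset mismatch — never as a silently "valid" file.
* **Degenerate inputs.** An empty collection writes a header-only container
  and decompresses to zero reads; `bits per base` is reported as `NA`.
  Buckets at depth $L$ hold only identical reads and are exempt from
  bursting (no distinguishing base remains).
* **Alphabet policy.** Lowercase bases are uppercased on read-in (lossy
  only with respect to soft-masking case). IUPAC ambiguity codes other than
  N are rejected rather than coerced, since coercion would lose
  information silently.

## The synthetic generator

`generate_reads()` emulates the two features real short-read data has that
the method exploits: a **constrained read space** (coverage mode draws reads
as windows of one random backing sequence — 15× coverage of a 50 kb
sequence is the test suite's standard high-redundancy condition) and
**exact duplicates** (a configurable fraction of reads are copies,
mimicking PCR and high-expression effects). Uncalled bases are placed
independently per base (default rate 0.01, typical of the ambiguity
fraction in public short-read runs). What it does **not** emulate:
sequencing-error substitution structure, quality correlation, paired-end
structure, and the repeat content of real genomes (a random backing
sequence has only chance repeats). Passing tests therefore demonstrate
correctness (losslessness, ordering, format integrity) on realistic
*redundancy*, and indicative — not benchmark — compression rates: on the
15×-coverage condition the suite requires under 2 bits per base and
typically observes ≈ 1.5; published rates on real runs depend on the
dataset.

The suite's problem sizes (10⁵-read sorting sweeps, a few thousand reads
per end-to-end grid cell) were chosen as the smallest sizes that exercise
bursting, partitioning and the statistical checks meaningfully.

## Known limitations

* Only the delta to the *previous* read is exploited; similarity between
  reads far apart in sort order (e.g. the suffix of one read matching the
  prefix of another) is invisible to the coder, so relative efficiency
  degrades as reads get longer and the read space less saturated.
* Fixed read length is required; variable-length collections are refused.
* Quality scores and read names are out of scope by design.
* Compression of a single block is sequential; block-level parallelism is
  possible in the format but not implemented here.
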