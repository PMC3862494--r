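#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

constexpr double TWO53 = 9007199254740992.0; // 2^53, exact-double limit

int base_code[256];
struct BaseCodeInit {
  BaseCodeInit() {
    std::fill(std::begin(base_code), std::end(base_code), -1);
    base_code[(unsigned char)'A'] = 0;
    base_code[(unsigned char)'C'] = 1;
    base_code[(unsigned char)'G'] = 2;
    base_code[(unsigned char)'T'] = 3;
  }
} base_code_init;

const char BASES[] = "ACGT";

// ---------------------------------------------------------------------------
// Bit-level I/O, most-significant-bit-first. The first appended bit occupies
// the highest bit of the first byte; zero padding only at block ends.
// ---------------------------------------------------------------------------

struct BitWriter {
  std::vector<uint8_t> bytes;
  size_t nbits = 0;
  void put(int b) {
    size_t bp = nbits & 7;
    if (bp == 0) bytes.push_back(0);
    if (b) bytes.back() |= (uint8_t)(0x80u >> bp);
    ++nbits;
  }
};

struct BitReader {
  const uint8_t* p;
  size_t nbits;
  size_t pos;
  BitReader(const uint8_t* p_, size_t nbits_) : p(p_), nbits(nbits_), pos(0) {}
  int get() {
    if (pos >= nbits)
      stop("truncated bitstream: codeword runs past end of stream");
    int b = (p[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
};

inline int bitlen_u64(uint64_t v) { return 64 - __builtin_clzll(v); }

// ---------------------------------------------------------------------------
// Elias omega code, 64-bit values.
//
// Encode n: start from the terminator bit 0; while n > 1, prefix the binary
// representation of n and replace n by floor(log2 n). Decode runs the loop
// forward: a leading 1 means "read n more bits", which together with an
// implicit leading 1 form the next, larger n; a 0 stops.
// ---------------------------------------------------------------------------

void omega_emit_u64(uint64_t n, BitWriter& w) {
  uint64_t chain[8];
  int k = 0;
  while (n > 1) {
    chain[k++] = n;
    n = (uint64_t)(bitlen_u64(n) - 1);
  }
  for (int i = k - 1; i >= 0; --i) {
    int len = bitlen_u64(chain[i]);
    for (int j = len - 1; j >= 0; --j) w.put((chain[i] >> j) & 1);
  }
  w.put(0);
}

uint64_t omega_read_u64(BitReader& r) {
  uint64_t n = 1;
  while (r.get()) {
    if (n > 63)
      stop("codeword value exceeds the 64-bit range of this decoder");
    uint64_t v = 1;
    for (uint64_t i = 0; i < n; ++i) v = (v << 1) | (uint64_t)r.get();
    n = v;
  }
  return n;
}

// ---------------------------------------------------------------------------
// Fixed-width big integers as little-endian 64-bit limbs. A read of length L
// packs to a 2L-bit value; deltas need up to 2L+1 bits. All vectors passed to
// these helpers share one width chosen per block.
// ---------------------------------------------------------------------------

typedef std::vector<uint64_t> Big;

int big_bitlen(const Big& v) {
  for (int i = (int)v.size() - 1; i >= 0; --i)
    if (v[i]) return 64 * i + bitlen_u64(v[i]);
  return 0;
}

inline int big_getbit(const Big& v, int i) {
  return (int)((v[i >> 6] >> (i & 63)) & 1);
}

inline void big_shl1(Big& v) {
  uint64_t carry = 0;
  for (size_t i = 0; i < v.size(); ++i) {
    uint64_t nc = v[i] >> 63;
    v[i] = (v[i] << 1) | carry;
    carry = nc;
  }
}

// a - b -> out; returns final borrow (1 means b > a)
uint64_t big_sub(const Big& a, const Big& b, Big& out) {
  uint64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t bi = b[i] + borrow;
    uint64_t nb = (bi < b[i]) || (a[i] < bi);
    out[i] = a[i] - bi;
    borrow = nb;
  }
  return borrow;
}

void big_add(Big& a, const Big& b) {
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = a[i] + b[i];
    uint64_t c1 = s < a[i];
    a[i] = s + carry;
    carry = c1 + (a[i] < s);
  }
}

void big_add1(Big& v) {
  for (size_t i = 0; i < v.size(); ++i)
    if (++v[i]) return;
}

void big_sub1(Big& v) {
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i]--) return;
  }
}

void omega_emit_big(const Big& v, BitWriter& w) {
  int b = big_bitlen(v);
  if (b == 0) stop("internal error: zero has no Elias omega codeword");
  if (b > 1) {
    uint64_t chain[8];
    int k = 0;
    uint64_t n = (uint64_t)(b - 1);
    while (n > 1) {
      chain[k++] = n;
      n = (uint64_t)(bitlen_u64(n) - 1);
    }
    for (int i = k - 1; i >= 0; --i) {
      int len = bitlen_u64(chain[i]);
      for (int j = len - 1; j >= 0; --j) w.put((chain[i] >> j) & 1);
    }
    for (int i = b - 1; i >= 0; --i) w.put(big_getbit(v, i));
  }
  w.put(0);
}

// Decodes one codeword into `out` (width fixed); values above maxbits bits
// are rejected, which also guards against corrupt streams requesting an
// absurd number of continuation bits.
void omega_read_big(BitReader& r, Big& out, int maxbits) {
  std::fill(out.begin(), out.end(), 0);
  out[0] = 1;
  int curbits = 1;
  while (r.get()) {
    if (curbits > 32)
      stop("corrupt stream: codeword length prefix is implausibly large");
    uint64_t n = out[0];
    if (n > (uint64_t)maxbits)
      stop("corrupt stream: codeword exceeds the declared read length");
    std::fill(out.begin(), out.end(), 0);
    out[0] = 1;
    for (uint64_t i = 0; i < n; ++i) {
      big_shl1(out);
      out[0] |= (uint64_t)r.get();
    }
    curbits = (int)n + 1;
  }
}

void read_to_big(const char* s, int L, Big& v) {
  std::fill(v.begin(), v.end(), 0);
  for (int i = 0; i < L; ++i) {
    int d = base_code[(unsigned char)s[i]];
    if (d < 0)
      stop("invalid base '%c' (only A, C, G, T allowed here)", s[i]);
    big_shl1(v);
    big_shl1(v);
    v[0] |= (uint64_t)d;
  }
}

void big_to_read(const Big& v, int L, std::string& s) {
  for (int i = 0; i < L; ++i) {
    int pos = 2 * (L - 1 - i);
    int d = big_getbit(v, pos) | (big_getbit(v, pos + 1) << 1);
    s[i] = BASES[d];
  }
}

NumericVector check_positive_integers(NumericVector values) {
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    double v = values[i];
    if (ISNAN(v) || v < 1 || v != std::floor(v))
      stop("all values must be positive integers (no Elias omega code exists for zero)");
    if (v > TWO53)
      stop("values above 2^53 are not exactly representable as R doubles");
  }
  return values;
}

} // namespace

// ---------------------------------------------------------------------------
// Exported: omega codec on explicit 0/1 bit vectors (the testing/teaching
// surface) and on packed byte streams (the pipeline surface).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_omega_encode_bits(NumericVector values) {
  check_positive_integers(values);
  BitWriter w;
  for (R_xlen_t i = 0; i < values.size(); ++i)
    omega_emit_u64((uint64_t)values[i], w);
  IntegerVector bits((R_xlen_t)w.nbits);
  for (size_t i = 0; i < w.nbits; ++i)
    bits[i] = (w.bytes[i >> 3] >> (7 - (i & 7))) & 1;
  return bits;
}

// [[Rcpp::export]]
NumericVector cpp_omega_decode_bits(IntegerVector bits, double count) {
  std::vector<uint8_t> bytes((bits.size() + 7) / 8, 0);
  for (R_xlen_t i = 0; i < bits.size(); ++i) {
    int b = bits[i];
    if (b != 0 && b != 1) stop("bitstream must contain only 0s and 1s");
    if (b) bytes[i >> 3] |= (uint8_t)(0x80u >> (i & 7));
  }
  BitReader r(bytes.data(), (size_t)bits.size());
  R_xlen_t n = (R_xlen_t)count;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = omega_read_u64(r);
    if (v > (uint64_t)TWO53)
      stop("decoded value exceeds 2^53 and cannot be returned exactly");
    out[i] = (double)v;
  }
  out.attr("nbits") = (double)r.pos;
  return out;
}

// [[Rcpp::export]]
List cpp_omega_stream_encode(NumericVector values) {
  check_positive_integers(values);
  BitWriter w;
  for (R_xlen_t i = 0; i < values.size(); ++i)
    omega_emit_u64((uint64_t)values[i], w);
  RawVector bytes(w.bytes.size());
  if (!w.bytes.empty()) std::memcpy(&bytes[0], w.bytes.data(), w.bytes.size());
  return List::create(_["bytes"] = bytes, _["nbits"] = (double)w.nbits);
}

// [[Rcpp::export]]
NumericVector cpp_omega_stream_decode(RawVector bytes, double nbits, double count) {
  if (nbits > (double)bytes.size() * 8)
    stop("corrupt stream: bit count exceeds byte payload");
  BitReader r(bytes.size() ? (const uint8_t*)&bytes[0] : nullptr, (size_t)nbits);
  R_xlen_t n = (R_xlen_t)count;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = omega_read_u64(r);
    if (v > (uint64_t)TWO53)
      stop("decoded value exceeds 2^53 and cannot be returned exactly");
    out[i] = (double)v;
  }
  if (r.pos != (size_t)nbits)
    stop("corrupt stream: %d unread bits after the declared codeword count",
         (int)((size_t)nbits - r.pos));
  return out;
}

// ---------------------------------------------------------------------------
// Exported: sorted-read stream codec. Packs each read into a 2L-bit integer
// (A=00, C=01, G=10, T=11), takes successive differences plus one (d1 = r1+1)
// and emits one omega codeword per read; unbounded in L via limb arithmetic.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_encode_reads(CharacterVector reads) {
  R_xlen_t n = reads.size();
  BitWriter w;
  if (n > 0) {
    int L = (int)std::strlen(CHAR(STRING_ELT(reads, 0)));
    if (L < 1) stop("reads must have length >= 1");
    int nw = (2 * L + 1 + 63) / 64 + 1;
    Big prev(nw, 0), cur(nw, 0), d(nw, 0);
    for (R_xlen_t i = 0; i < n; ++i) {
      const char* s = CHAR(STRING_ELT(reads, i));
      if ((int)std::strlen(s) != L)
        stop("read %d has a different length; reads must be uniform", (int)(i + 1));
      read_to_big(s, L, cur);
      if (big_sub(cur, prev, d))
        stop("reads are not in sorted order at position %d", (int)(i + 1));
      big_add1(d);
      omega_emit_big(d, w);
      std::swap(prev, cur);
    }
  }
  RawVector bytes(w.bytes.size());
  if (!w.bytes.empty()) std::memcpy(&bytes[0], w.bytes.data(), w.bytes.size());
  return List::create(_["bytes"] = bytes, _["nbits"] = (double)w.nbits);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_reads(RawVector bytes, double nbits, double count, int L) {
  if (L < 1) stop("read length must be >= 1");
  if (nbits > (double)bytes.size() * 8)
    stop("corrupt stream: bit count exceeds byte payload");
  R_xlen_t n = (R_xlen_t)count;
  BitReader r(bytes.size() ? (const uint8_t*)&bytes[0] : nullptr, (size_t)nbits);
  int nw = (2 * L + 1 + 63) / 64 + 1;
  Big prev(nw, 0), d(nw, 0);
  std::string s((size_t)L, 'A');
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    omega_read_big(r, d, 2 * L + 1);
    big_sub1(d);
    big_add(prev, d);
    if (big_bitlen(prev) > 2 * L)
      stop("corrupt stream: decoded value exceeds the read-length range");
    big_to_read(prev, L, s);
    out[i] = s;
  }
  if (r.pos != (size_t)nbits)
    stop("corrupt stream: %d unread bits after the declared read count",
         (int)((size_t)nbits - r.pos));
  return out;
}

// ---------------------------------------------------------------------------
// Burst trie. Trie nodes hold four child slots (A,C,G,T); small subtrees are
// growable buckets of read indices sharing a common prefix. A bucket pushed
// past capacity bursts into a node one level deeper; buckets at depth L hold
// identical reads and are exempt. In-order traversal with a stable suffix
// sort inside each bucket yields a stable lexicographic sort of the input.
// ---------------------------------------------------------------------------

namespace {

struct BTBucket {
  std::vector<int> idx;
};

struct BTNode {
  void* ch[4];
  uint8_t t[4]; // 0 = empty, 1 = bucket, 2 = node
  BTNode() {
    ch[0] = ch[1] = ch[2] = ch[3] = nullptr;
    t[0] = t[1] = t[2] = t[3] = 0;
  }
};

void free_subtree(BTNode* nd) {
  for (int c = 0; c < 4; ++c) {
    if (nd->t[c] == 1)
      delete (BTBucket*)nd->ch[c];
    else if (nd->t[c] == 2)
      free_subtree((BTNode*)nd->ch[c]);
  }
  delete nd;
}

struct BurstTrie {
  BTNode* root;
  int capacity;
  int L;
  std::vector<std::string> reads;
  long nodes, buckets, bursts;
  explicit BurstTrie(int cap)
      : root(new BTNode()), capacity(cap), L(-1), nodes(1), buckets(0), bursts(0) {}
  ~BurstTrie() { free_subtree(root); }

  // bucket at nd->ch[c] has depth pdepth + 1
  void burst(BTNode* nd, int c, int pdepth) {
    BTBucket* b = (BTBucket*)nd->ch[c];
    int bd = pdepth + 1;
    BTNode* nn = new BTNode();
    ++nodes;
    ++bursts;
    --buckets;
    for (int i : b->idx) {
      int d = base_code[(unsigned char)reads[(size_t)i][(size_t)bd]];
      if (nn->t[d] == 0) {
        nn->ch[d] = new BTBucket();
        nn->t[d] = 1;
        ++buckets;
      }
      ((BTBucket*)nn->ch[d])->idx.push_back(i);
    }
    delete b;
    nd->ch[c] = nn;
    nd->t[c] = 2;
    for (int d = 0; d < 4; ++d) {
      if (nn->t[d] == 1 &&
          (int)((BTBucket*)nn->ch[d])->idx.size() > capacity && bd + 1 < L)
        burst(nn, d, bd);
    }
  }

  void insert(int i) {
    const std::string& s = reads[(size_t)i];
    BTNode* nd = root;
    int depth = 0;
    for (;;) {
      int c = base_code[(unsigned char)s[(size_t)depth]];
      if (c < 0)
        stop("invalid base '%c' in read %d (substitute N before sorting)",
             s[(size_t)depth], i + 1);
      if (nd->t[c] == 0) {
        BTBucket* b = new BTBucket();
        b->idx.push_back(i);
        nd->ch[c] = b;
        nd->t[c] = 1;
        ++buckets;
        return;
      }
      if (nd->t[c] == 2) {
        nd = (BTNode*)nd->ch[c];
        ++depth;
        continue;
      }
      BTBucket* b = (BTBucket*)nd->ch[c];
      b->idx.push_back(i);
      if ((int)b->idx.size() > capacity && depth + 1 < L) burst(nd, c, depth);
      return;
    }
  }

  void traverse(BTNode* nd, int depth, std::vector<int>& out) const {
    for (int c = 0; c < 4; ++c) {
      if (nd->t[c] == 2) {
        traverse((BTNode*)nd->ch[c], depth + 1, out);
      } else if (nd->t[c] == 1) {
        const BTBucket* b = (const BTBucket*)nd->ch[c];
        std::vector<int> v(b->idx);
        int off = depth + 1; // shared prefix length of this bucket
        if (off < L) {
          const std::vector<std::string>& rd = reads;
          int len = L - off;
          std::stable_sort(v.begin(), v.end(), [&rd, off, len](int a, int bb) {
            return std::memcmp(rd[(size_t)a].data() + off,
                               rd[(size_t)bb].data() + off, (size_t)len) < 0;
          });
        }
        out.insert(out.end(), v.begin(), v.end());
      }
    }
  }
};

List structure_of(const BurstTrie& bt, BTNode* nd, int depth);

List structure_of_child(const BurstTrie& bt, BTNode* nd, int c, int depth) {
  if (nd->t[c] == 2) return structure_of(bt, (BTNode*)nd->ch[c], depth + 1);
  const BTBucket* b = (const BTBucket*)nd->ch[c];
  CharacterVector entries(b->idx.size());
  for (size_t i = 0; i < b->idx.size(); ++i)
    entries[(R_xlen_t)i] = bt.reads[(size_t)b->idx[i]];
  return List::create(_["type"] = "bucket", _["depth"] = depth + 1,
                      _["reads"] = entries);
}

List structure_of(const BurstTrie& bt, BTNode* nd, int depth) {
  List ch;
  CharacterVector nm;
  for (int c = 0; c < 4; ++c) {
    if (nd->t[c] != 0) {
      ch.push_back(structure_of_child(bt, nd, c, depth));
      nm.push_back(std::string(1, BASES[c]));
    }
  }
  ch.attr("names") = nm;
  return List::create(_["type"] = "node", _["depth"] = depth,
                      _["children"] = ch);
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_bt_new(int capacity) {
  if (capacity < 1) stop("bucket capacity must be >= 1");
  XPtr<BurstTrie> p(new BurstTrie(capacity), true);
  return p;
}

// [[Rcpp::export]]
void cpp_bt_insert(SEXP xp, CharacterVector reads) {
  XPtr<BurstTrie> bt(xp);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = (int)std::strlen(s);
    if (bt->L < 0) {
      if (len < 1) stop("reads must have length >= 1");
      bt->L = len;
    } else if (len != bt->L) {
      stop("read of length %d does not match trie read length %d", len, bt->L);
    }
    for (int j = 0; j < len; ++j)
      if (base_code[(unsigned char)s[j]] < 0)
        stop("invalid base '%c' in read %d (substitute N before sorting)",
             s[j], (int)(i + 1));
    bt->reads.push_back(std::string(s));
    bt->insert((int)bt->reads.size() - 1);
  }
}

// [[Rcpp::export]]
List cpp_bt_stats(SEXP xp) {
  XPtr<BurstTrie> bt(xp);
  return List::create(
      _["read_count"] = (double)bt->reads.size(),
      _["read_length"] = bt->L < 0 ? NA_INTEGER : bt->L,
      _["capacity"] = bt->capacity, _["trie_nodes"] = (double)bt->nodes,
      _["buckets"] = (double)bt->buckets, _["bursts"] = (double)bt->bursts);
}

// [[Rcpp::export]]
IntegerVector cpp_bt_order(SEXP xp) {
  XPtr<BurstTrie> bt(xp);
  std::vector<int> out;
  out.reserve(bt->reads.size());
  bt->traverse(bt->root, 0, out);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[(R_xlen_t)i] = out[i] + 1;
  return res;
}

// [[Rcpp::export]]
CharacterVector cpp_bt_sorted(SEXP xp) {
  XPtr<BurstTrie> bt(xp);
  std::vector<int> ord;
  ord.reserve(bt->reads.size());
  bt->traverse(bt->root, 0, ord);
  CharacterVector res(ord.size());
  for (size_t i = 0; i < ord.size(); ++i)
    res[(R_xlen_t)i] = bt->reads[(size_t)ord[i]];
  return res;
}

// [[Rcpp::export]]
List cpp_bt_structure(SEXP xp) {
  XPtr<BurstTrie> bt(xp);
  return structure_of(*bt, bt->root, 0);
}
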