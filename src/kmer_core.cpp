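// Core k-mer machinery: 2-bit encoding, reverse complement by bit arithmetic,
// canonical hashing with DJB2, the half-flipped linear-probing table, genome
// enumeration, Hamming-neighborhood near-match search, and read counting.
// All 64-bit k-mer values stay on this side of the fence; R sees them as
// 8-byte big-endian raw vectors (R doubles lose exactness past 2^53).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <thread>

using namespace Rcpp;

// ---------------------------------------------------------------- encoding

// Base code = bits 1-2 of the ASCII character: A->0, C->1, T->2, G->3.
// This makes complementation (code - 2) mod 4, i.e. XOR with 0b10.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 3;
    case 'T': case 't': return 2;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'T', 'G'};

static inline uint64_t kmask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// Reverse the order of 2-bit groups within one byte.
struct Rev2Table {
  uint8_t t[256];
  Rev2Table() {
    for (int b = 0; b < 256; ++b)
      t[b] = (uint8_t)(((b & 3) << 6) | (((b >> 2) & 3) << 4) |
                       (((b >> 4) & 3) << 2) | ((b >> 6) & 3));
  }
};
static const Rev2Table REV2;

// Reverse complement of a 2-bit packed k-mer. Complement each 2-bit slot
// (XOR 0b10 per slot), reverse slot order over 64 bits (byte swap + per-byte
// 2-bit reversal), then right-align to 2k bits.
static inline uint64_t revcomp64(uint64_t v, int k) {
  uint64_t x = (v ^ 0xAAAAAAAAAAAAAAAAULL) & kmask(k);
  uint64_t r = 0;
  for (int i = 0; i < 8; ++i) {
    r = (r << 8) | REV2.t[x & 0xFF];
    x >>= 8;
  }
  return r >> (64 - 2 * k);
}

static inline uint64_t canonical64(uint64_t v, int k) {
  uint64_t rc = revcomp64(v, k);
  return rc < v ? rc : v;
}

// Classic multiplicative DJB2 (h = h*33 + byte, seed 5381, 64-bit wrap) over
// the 8 bytes of the value, most-significant byte first.
static inline uint64_t djb2_u64(uint64_t v) {
  uint64_t h = 5381ULL;
  for (int i = 7; i >= 0; --i)
    h = h * 33ULL + ((v >> (8 * i)) & 0xFFULL);
  return h;
}

static inline uint64_t djb2_bytes(const uint8_t *p, size_t n) {
  uint64_t h = 5381ULL;
  for (size_t i = 0; i < n; ++i) h = h * 33ULL + p[i];
  return h;
}

// raw <-> uint64, big-endian (byte 0 is the most significant)
static inline uint64_t raw_to_u64(const uint8_t *p) {
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v = (v << 8) | p[i];
  return v;
}
static inline void u64_to_raw(uint64_t v, uint8_t *p) {
  for (int i = 7; i >= 0; --i) { p[i] = (uint8_t)(v & 0xFF); v >>= 8; }
}

static uint64_t rv_to_u64(const RawVector &r) {
  if (r.size() != 8) stop("encoded k-mer value must be 8 bytes");
  return raw_to_u64(RAW(r));
}
static RawVector u64_to_rv(uint64_t v) {
  RawVector r(8);
  u64_to_raw(v, RAW(r));
  return r;
}

static std::vector<uint64_t> rawvec_to_u64s(const RawVector &r) {
  if (r.size() % 8 != 0) stop("value buffer length must be a multiple of 8");
  size_t n = r.size() / 8;
  std::vector<uint64_t> out(n);
  const uint8_t *p = RAW(r);
  for (size_t i = 0; i < n; ++i) out[i] = raw_to_u64(p + 8 * i);
  return out;
}
static RawVector u64s_to_rawvec(const std::vector<uint64_t> &v) {
  RawVector r(8 * v.size());
  uint8_t *p = RAW(r);
  for (size_t i = 0; i < v.size(); ++i) u64_to_raw(v[i], p + 8 * i);
  return r;
}

// ------------------------------------------------------------- hash table

// Open-addressing table. Probes start at DJB2(key) mod capacity and advance
// toward increasing indices when the start lies in the lower half of the
// array, toward decreasing indices otherwise; no wraparound, so a probe can
// fall off an array edge (reported as PROBE_EDGE; callers resize and retry).
struct KTable {
  // separate key/flag/payload arrays: probes mostly touch keys_ and the
  // small used_ array, which stays cache-resident
  uint64_t capacity;
  std::vector<uint64_t> keys_;
  std::vector<uint8_t> used_;
  std::vector<int64_t> payload_;  // occurrence count, or catalog row index
  uint64_t n_occupied;

  static const long long ABSENT = -1;
  static const long long PROBE_EDGE = -2;

  explicit KTable(uint64_t cap)
      : capacity(cap), keys_(cap, 0), used_(cap, 0), payload_(cap, 0),
        n_occupied(0) {}

  bool used(long long idx) const { return used_[idx] != 0; }
  uint64_t key_at(long long idx) const { return keys_[idx]; }
  int64_t &payload(long long idx) { return payload_[idx]; }
  int64_t payload_at(long long idx) const { return payload_[idx]; }

  // Cell holding `key`, or the empty cell where it would go, or PROBE_EDGE.
  long long probe(uint64_t key) const {
    long long idx = (long long)(djb2_u64(key) % capacity);
    const int dir = (idx < (long long)(capacity / 2)) ? 1 : -1;
    while (idx >= 0 && idx < (long long)capacity) {
      if (!used_[idx] || keys_[idx] == key) return idx;
      idx += dir;
    }
    return PROBE_EDGE;
  }

  // Insert (or find) a key; returns cell index or PROBE_EDGE.
  long long insert(uint64_t key) {
    if (n_occupied >= capacity) return PROBE_EDGE;
    long long idx = probe(key);
    if (idx == PROBE_EDGE) return PROBE_EDGE;
    if (!used_[idx]) {
      used_[idx] = 1;
      keys_[idx] = key;
      payload_[idx] = 0;
      ++n_occupied;
    }
    return idx;
  }

  long long lookup(uint64_t key) const {
    long long idx = probe(key);
    if (idx == PROBE_EDGE || !used_[idx]) return ABSENT;
    return idx;
  }
};

static uint64_t next_pow2(uint64_t x) {
  uint64_t p = 1;
  while (p < x) p <<= 1;
  return p;
}

// Capacity = next power of two >= 2 * n_keys (load factor <= 0.5). A probe
// can still in principle run off an edge; build_table() grows until clean.
static uint64_t size_for(uint64_t n_keys) {
  uint64_t want = 2 * (n_keys < 2 ? 2 : n_keys);
  return next_pow2(want);
}

// Build a table over a fixed key set with payload = running index, growing
// on probe-edge overflow.
static KTable build_table(const std::vector<uint64_t> &keys_in,
                          const std::vector<int64_t> *payload_in) {
  uint64_t cap = size_for(keys_in.size());
  for (;;) {
    KTable t(cap);
    bool ok = true;
    for (size_t i = 0; i < keys_in.size(); ++i) {
      long long c = t.insert(keys_in[i]);
      if (c == KTable::PROBE_EDGE) { ok = false; break; }
      t.payload(c) = payload_in ? (*payload_in)[i] : (int64_t)i;
    }
    if (ok) return t;
    cap <<= 1;
  }
}

// ------------------------------------------------------ R-facing codec ops

// [[Rcpp::export]]
SEXP cpp_encode(std::string seq) {
  int k = (int)seq.size();
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) return R_NilValue;  // reject signal (N / ambiguity code)
    v = (v << 2) | (uint64_t)c;
  }
  return u64_to_rv(v);
}

// [[Rcpp::export]]
std::string cpp_decode(RawVector value, int k) {
  uint64_t v = rv_to_u64(value);
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = CODE2BASE[v & 3];
    v >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_many(RawVector values, int k) {
  std::vector<uint64_t> v = rawvec_to_u64s(values);
  CharacterVector out(v.size());
  std::string s(k, 'A');
  for (size_t j = 0; j < v.size(); ++j) {
    uint64_t x = v[j];
    for (int i = k - 1; i >= 0; --i) { s[i] = CODE2BASE[x & 3]; x >>= 2; }
    out[j] = s;
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_revcomp(RawVector value, int k) {
  return u64_to_rv(revcomp64(rv_to_u64(value), k));
}

// [[Rcpp::export]]
RawVector cpp_canonical(RawVector value, int k) {
  return u64_to_rv(canonical64(rv_to_u64(value), k));
}

// [[Rcpp::export]]
RawVector cpp_canonical_many(RawVector values, int k) {
  std::vector<uint64_t> v = rawvec_to_u64s(values);
  for (size_t i = 0; i < v.size(); ++i) v[i] = canonical64(v[i], k);
  return u64s_to_rawvec(v);
}

// DJB2 over arbitrary bytes, returned as 8 raw bytes (big-endian).
// [[Rcpp::export]]
RawVector cpp_djb2(RawVector bytes) {
  return u64_to_rv(djb2_bytes(RAW(bytes), bytes.size()));
}

// [[Rcpp::export]]
std::string cpp_djb2_hex(RawVector bytes) {
  uint64_t h = djb2_bytes(RAW(bytes), bytes.size());
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// [[Rcpp::export]]
double cpp_hash_index(RawVector value, double capacity) {
  if (capacity < 1) stop("capacity must be >= 1");
  uint64_t cap = (uint64_t)capacity;
  return (double)(djb2_u64(rv_to_u64(value)) % cap);
}

// ----------------------------------------------- R-facing hash table (tests)

// [[Rcpp::export]]
SEXP cpp_table_new(double capacity) {
  if (capacity < 1) stop("capacity must be >= 1");
  XPtr<KTable> p(new KTable((uint64_t)capacity), true);
  return p;
}

// [[Rcpp::export]]
double cpp_table_insert(SEXP tp, RawVector value) {
  XPtr<KTable> t(tp);
  if (t->n_occupied >= t->capacity - 1)
    stop("hash table capacity exceeded");  // keep >= 1 empty cell
  long long c = t->insert(rv_to_u64(value));
  if (c == KTable::PROBE_EDGE)
    stop("hash table capacity exceeded (probe reached array edge)");
  return (double)c;
}

// [[Rcpp::export]]
double cpp_table_lookup(SEXP tp, RawVector value) {
  XPtr<KTable> t(tp);
  long long c = t->lookup(rv_to_u64(value));
  return c == KTable::ABSENT ? -1.0 : (double)c;
}

// [[Rcpp::export]]
double cpp_table_occupancy(SEXP tp) {
  XPtr<KTable> t(tp);
  return (double)t->n_occupied;
}

// --------------------------------------------------------- genome scanning

// Visitor over all valid (ACGT-only) k-mer windows of one sequence.
// cb(start, canonical_value)
template <typename F>
static void scan_windows(const char *s, size_t n, int k, F cb) {
  uint64_t v = 0;
  const uint64_t mask = kmask(k);
  int run = 0;  // length of current ACGT run ending at i
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t)c) & mask;
    if (++run >= k) cb(i + 1 - k, canonical64(v, k));
  }
}

// Enumerate all k-mer occurrences of a genome under canonical encoding.
// Returns distinct canonical values in first-appearance order, their
// occurrence counts, and an external pointer to the lookup table
// (payload = index into the values vector).
// [[Rcpp::export]]
List cpp_enumerate(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  // first pass: upper bound on distinct keys = total windows
  uint64_t total_windows = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    R_xlen_t len = LENGTH(STRING_ELT(seqs, i));
    if (len >= k) total_windows += (uint64_t)(len - k + 1);
  }
  uint64_t cap = size_for(total_windows);
  for (;;) {
    KTable t(cap);
    std::vector<uint64_t> order;
    order.reserve(total_windows / 2 + 16);
    bool ok = true;
    for (R_xlen_t i = 0; i < seqs.size() && ok; ++i) {
      const char *s = CHAR(STRING_ELT(seqs, i));
      size_t n = (size_t)LENGTH(STRING_ELT(seqs, i));
      uint64_t v = 0;
      const uint64_t mask = kmask(k);
      int run = 0;
      for (size_t j = 0; j < n; ++j) {
        int c = base_code(s[j]);
        if (c < 0) { run = 0; v = 0; continue; }
        v = ((v << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        uint64_t can = canonical64(v, k);
        long long cell = t.insert(can);
        if (cell == KTable::PROBE_EDGE) { ok = false; break; }
        // payload accumulates the occurrence count; first touch records
        // the value so output order is first-appearance (genome) order
        if (t.payload(cell) == 0) order.push_back(can);
        t.payload(cell) += 1;
      }
    }
    if (!ok) { cap <<= 1; continue; }
    NumericVector counts(order.size());
    for (size_t i = 0; i < order.size(); ++i) {
      long long cell = t.lookup(order[i]);
      counts[i] = (double)t.payload_at(cell);
    }
    // repoint payload at the order index so downstream lookups are O(1)
    for (size_t i = 0; i < order.size(); ++i) {
      long long cell = t.lookup(order[i]);
      t.payload(cell) = (int64_t)i;
    }
    XPtr<KTable> p(new KTable(std::move(t)), true);
    return List::create(_["values"] = u64s_to_rawvec(order),
                        _["counts"] = counts,
                        _["ptr"] = p);
  }
}

// ------------------------------------------------- near-match (edit) search

// Fast avalanche mixer for the internal dedup set only (the table hash
// stays DJB2 per the probing contract).
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Fixed-size open hash set with generation stamps (cleared in O(1)).
struct ScratchSet {
  std::vector<uint64_t> key;
  std::vector<uint32_t> gen;
  uint32_t cur;
  size_t mask;
  explicit ScratchSet(size_t cap_pow2)
      : key(cap_pow2, 0), gen(cap_pow2, 0), cur(0), mask(cap_pow2 - 1) {}
  void clear() { ++cur; }
  // returns true if newly added
  bool add(uint64_t k) {
    size_t i = (size_t)mix64(k) & mask;
    for (;;) {
      if (gen[i] != cur) { gen[i] = cur; key[i] = k; return true; }
      if (key[i] == k) return false;
      i = (i + 1) & mask;
    }
  }
};

// Near-match count for one candidate: total genome occurrences of all
// distinct canonical k-mers at substitution distance 1..j from the
// candidate, excluding the candidate itself. Each variant's reverse
// complement is maintained incrementally: substituting code c at position p
// of the forward strand substitutes c^2 at mirrored slot p of the reverse
// complement.
static double near_count_core(uint64_t cand, int k, int j, const KTable &tab,
                              const double *cnt, size_t nc,
                              ScratchSet &seen) {
  if (j <= 0) return 0.0;
  seen.clear();
  seen.add(cand);
  const uint64_t crc = revcomp64(cand, k);
  double total = 0.0;
  auto tally = [&](uint64_t v, uint64_t vrc) {
    uint64_t can = vrc < v ? vrc : v;
    if (!seen.add(can)) return;
    long long cell = tab.lookup(can);
    if (cell != KTable::ABSENT) {
      size_t ix = (size_t)tab.payload_at(cell);
      if (ix < nc) total += cnt[ix];
    }
  };
  for (int p1 = 0; p1 < k; ++p1) {
    const int s1 = 2 * (k - 1 - p1);
    const int r1 = 2 * p1;
    const uint64_t o1 = (cand >> s1) & 3ULL;
    for (uint64_t c1 = 0; c1 < 4; ++c1) {
      if (c1 == o1) continue;
      const uint64_t v1 = (cand & ~(3ULL << s1)) | (c1 << s1);
      const uint64_t v1rc = (crc & ~(3ULL << r1)) | ((c1 ^ 2ULL) << r1);
      tally(v1, v1rc);
      if (j < 2) continue;
      // distance 2: second substitution strictly 3' of the first
      for (int p2 = p1 + 1; p2 < k; ++p2) {
        const int s2 = 2 * (k - 1 - p2);
        const int r2 = 2 * p2;
        const uint64_t o2 = (v1 >> s2) & 3ULL;
        for (uint64_t c2 = 0; c2 < 4; ++c2) {
          if (c2 == o2) continue;
          tally((v1 & ~(3ULL << s2)) | (c2 << s2),
                (v1rc & ~(3ULL << r2)) | ((c2 ^ 2ULL) << r2));
        }
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_near_counts(RawVector cand_values, SEXP occ_ptr,
                              NumericVector counts, int k, int j,
                              int threads) {
  XPtr<KTable> occ(occ_ptr);
  std::vector<uint64_t> cands = rawvec_to_u64s(cand_values);
  if (j < 0 || j > 2) stop("edit distance j must be 0, 1, or 2");
  if (threads < 1) threads = 1;
  const size_t n = cands.size();
  const KTable *tab = occ.get();
  const double *cnt = REAL(counts);
  const size_t nc = counts.size();
  NumericVector out(n);
  if (threads == 1 || n < 1024) {
    ScratchSet seen(8192);
    for (size_t i = 0; i < n; ++i)
      out[i] = near_count_core(cands[i], k, j, *tab, cnt, nc, seen);
    return out;
  }
  std::vector<double> res(n);
  std::vector<std::thread> pool;
  const size_t chunk = (n + threads - 1) / threads;
  for (int w = 0; w < threads; ++w) {
    size_t lo = (size_t)w * chunk, hi = std::min(n, lo + chunk);
    if (lo >= hi) break;
    pool.emplace_back([&, lo, hi]() {
      ScratchSet seen(8192);
      for (size_t i = lo; i < hi; ++i)
        res[i] = near_count_core(cands[i], k, j, *tab, cnt, nc, seen);
    });
  }
  for (auto &th : pool) th.join();
  for (size_t i = 0; i < n; ++i) out[i] = res[i];
  return out;
}

// Quadratic all-pairs Hamming oracle (reference implementation for tests):
// for each candidate, sums genome occurrence counts of every distinct
// canonical genome k-mer whose strand-minimized substitution distance from
// the candidate is 1..1 (column 1) or 1..2 (column 2). Shares no logic with
// the neighborhood-enumeration path above.
// [[Rcpp::export]]
NumericMatrix cpp_hamming_oracle(RawVector genome_values,
                                 NumericVector genome_counts,
                                 RawVector cand_values, int k) {
  std::vector<uint64_t> gv = rawvec_to_u64s(genome_values);
  std::vector<uint64_t> cv = rawvec_to_u64s(cand_values);
  const size_t ng = gv.size(), nc = cv.size();
  std::vector<uint64_t> grc(ng);
  for (size_t i = 0; i < ng; ++i) grc[i] = revcomp64(gv[i], k);
  NumericMatrix out(nc, 2);
  const uint64_t lowbits = 0x5555555555555555ULL & kmask(k);
  for (size_t ci = 0; ci < nc; ++ci) {
    uint64_t c = cv[ci];
    double n1 = 0.0, n2 = 0.0;
    for (size_t gi = 0; gi < ng; ++gi) {
      if (gv[gi] == c) continue;
      uint64_t x = c ^ gv[gi];
      int d = __builtin_popcountll((x | (x >> 1)) & lowbits);
      if (d > 2) {
        x = c ^ grc[gi];
        int d2 = __builtin_popcountll((x | (x >> 1)) & lowbits);
        if (d2 < d) d = d2;
      } else {
        uint64_t y = c ^ grc[gi];
        int d2 = __builtin_popcountll((y | (y >> 1)) & lowbits);
        if (d2 < d) d = d2;
      }
      if (d <= 2 && d >= 1) {
        n2 += genome_counts[gi];
        if (d == 1) n1 += genome_counts[gi];
      }
    }
    out(ci, 0) = n1;
    out(ci, 1) = n2;
  }
  return out;
}

// -------------------------------------------------------------- locating

// Locate each retained (genome-unique) canonical k-mer's single forward-
// strand occurrence. Returns 0-based chromosome index and start per value.
// [[Rcpp::export]]
List cpp_locate(CharacterVector seqs, int k, RawVector retained_values) {
  std::vector<uint64_t> keys = rawvec_to_u64s(retained_values);
  KTable t = build_table(keys, nullptr);
  const size_t n = keys.size();
  IntegerVector chrom(n, NA_INTEGER), start(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t len = (size_t)LENGTH(STRING_ELT(seqs, i));
    scan_windows(s, len, k, [&](size_t pos, uint64_t can) {
      long long cell = t.lookup(can);
      if (cell == KTable::ABSENT) return;
      size_t ix = (size_t)t.payload_at(cell);
      if (chrom[ix] != NA_INTEGER)
        stop("internal consistency error: retained k-mer found more than once");
      chrom[ix] = (int)i;
      start[ix] = (int)pos;
    });
  }
  for (size_t ix = 0; ix < n; ++ix)
    if (chrom[ix] == NA_INTEGER)
      stop("internal consistency error: retained k-mer not found in reference");
  return List::create(_["chrom"] = chrom, _["start"] = start);
}

// ------------------------------------------------------------ GC context

// GC fraction of the window_bp window centered on each k-mer's midpoint,
// clipped at sequence ends; denominator counts unambiguous bases only.
// [[Rcpp::export]]
NumericVector cpp_gc_fraction(std::string seq, IntegerVector starts, int k,
                              int window_bp) {
  const size_t n = seq.size();
  std::vector<int32_t> gc(n + 1, 0), acgt(n + 1, 0);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    gc[i + 1] = gc[i] + (c == 1 || c == 3 ? 1 : 0);
    acgt[i + 1] = acgt[i] + (c >= 0 ? 1 : 0);
  }
  NumericVector out(starts.size());
  const long long half = window_bp / 2;
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    long long center = (long long)starts[i] + k / 2;
    long long lo = center - half, hi = center + half;
    if (lo < 0) lo = 0;
    if (hi > (long long)n) hi = (long long)n;
    int denom = acgt[hi] - acgt[lo];
    out[i] = denom > 0 ? (double)(gc[hi] - gc[lo]) / denom : 0.5;
  }
  return out;
}

// ----------------------------------------------------------- read counting

struct Counter {
  KTable table;
  std::vector<int64_t> counts;
  int k;
  double total_reads, total_scanned;
  Counter(const std::vector<uint64_t> &keys, int k_)
      : table(build_table(keys, nullptr)), counts(keys.size(), 0), k(k_),
        total_reads(0), total_scanned(0) {}
};

// [[Rcpp::export]]
SEXP cpp_counter_new(RawVector catalog_values, int k) {
  std::vector<uint64_t> keys = rawvec_to_u64s(catalog_values);
  XPtr<Counter> p(new Counter(keys, k), true);
  return p;
}

// [[Rcpp::export]]
void cpp_counter_feed(SEXP cp, CharacterVector seqs) {
  XPtr<Counter> c(cp);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    size_t len = (size_t)LENGTH(STRING_ELT(seqs, i));
    c->total_reads += 1;
    scan_windows(s, len, c->k, [&](size_t, uint64_t can) {
      c->total_scanned += 1;
      long long cell = c->table.lookup(can);
      if (cell != KTable::ABSENT) c->counts[(size_t)c->table.payload_at(cell)]++;
    });
  }
}

// [[Rcpp::export]]
List cpp_counter_collect(SEXP cp) {
  XPtr<Counter> c(cp);
  NumericVector counts(c->counts.size());
  for (size_t i = 0; i < c->counts.size(); ++i)
    counts[i] = (double)c->counts[i];
  return List::create(_["counts"] = counts,
                      _["total_reads"] = c->total_reads,
                      _["total_kmers_scanned"] = c->total_scanned);
}
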