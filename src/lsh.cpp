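#include <Rcpp.h>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Seeded FNV-1a over the k-mer bytes with a splitmix64 finalizer. The finalizer
// matters: positions are taken mod L and plain FNV-1a has weak low bits.
static inline uint64_t fnv1a64(const char* s, int len, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ (seed * 0x9E3779B97F4A7C15ULL);
  for (int i = 0; i < len; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  h ^= h >> 30; h *= 0xBF58476D1CE4E5B9ULL;
  h ^= h >> 27; h *= 0x94D049BB133111EBULL;
  h ^= h >> 31;
  return h;
}

// [[Rcpp::export]]
IntegerVector hash_kmers_cpp(CharacterVector kmers, int L, int seed) {
  if (L < 1) stop("L must be >= 1");
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int len = LENGTH(STRING_ELT(kmers, i));
    out[i] = (int)(fnv1a64(s, len, (uint64_t)(int64_t)seed) % (uint64_t)L);
  }
  return out;
}

// Set positions (0-based, sorted, unique) of the LSH of one sequence.
// Windows at offsets 0..n-k-1: n-k windows, the final base never starts a window.
// [[Rcpp::export]]
IntegerVector lsh_positions_cpp(std::string seq, int k, int L, int seed) {
  int n = (int)seq.size();
  if (n <= k) stop("sequence length must exceed k");
  std::vector<char> filled((size_t)L, 0);
  const uint64_t sd = (uint64_t)(int64_t)seed;
  int n_windows = n - k;
  for (int off = 0; off < n_windows; ++off) {
    uint64_t h = fnv1a64(seq.data() + off, k, sd);
    filled[(size_t)(h % (uint64_t)L)] = 1;
  }
  int m = 0;
  for (int j = 0; j < L; ++j) m += filled[j];
  IntegerVector pos(m);
  for (int j = 0, i = 0; j < L; ++j) if (filled[j]) pos[i++] = j;
  return pos;
}

// Count of shared positions between two sorted integer vectors.
// [[Rcpp::export]]
int intersect_count_cpp(IntegerVector a, IntegerVector b) {
  R_xlen_t i = 0, j = 0;
  int count = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++count; ++i; ++j; }
  }
  return count;
}

// Empirical collision fraction: throw n_items distinct k-mers into L slots,
// return per-replicate fraction of items sharing a slot with another item.
// [[Rcpp::export]]
NumericVector collision_sim_cpp(int n_items, int L, int k, int reps, int seed) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  double space_d = std::pow(4.0, k);
  bool small_space = space_d <= 67108864.0; // 4^13
  uint64_t space = (uint64_t)space_d;
  if (small_space && (uint64_t)n_items > space)
    stop("n_items exceeds the number of distinct k-mers");
  std::mt19937_64 rng((uint64_t)(int64_t)seed);
  NumericVector out(reps);
  std::vector<uint32_t> pool;
  if (small_space) {
    pool.resize(space);
    for (uint64_t v = 0; v < space; ++v) pool[v] = (uint32_t)v;
  }
  std::vector<int> count((size_t)L);
  std::vector<int> slot((size_t)n_items);
  char kmer[32];
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int r = 0; r < reps; ++r) {
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n_items; ++i) {
      uint64_t code;
      if (small_space) { // partial Fisher-Yates: distinct k-mers guaranteed
        std::uniform_int_distribution<uint64_t> d(i, space - 1);
        uint64_t j = d(rng);
        std::swap(pool[i], pool[j]);
        code = pool[i];
      } else {
        code = rng() % space;
      }
      for (int b = 0; b < k; ++b) { kmer[b] = bases[code & 3]; code >>= 2; }
      int pos = (int)(fnv1a64(kmer, k, (uint64_t)(int64_t)seed) % (uint64_t)L);
      slot[i] = pos;
      count[pos]++;
    }
    int collided = 0;
    for (int i = 0; i < n_items; ++i) if (count[slot[i]] > 1) ++collided;
    out[r] = (double)collided / (double)n_items;
    if (small_space) // restore pool order cheaply for next replicate
      for (uint64_t v = 0; v < space; ++v) pool[v] = (uint32_t)v;
  }
  return out;
}
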