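#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Bitsets are packed into R integer vectors, 32 bits per word, reinterpreted
// as uint32_t. Bit b lives at word b >> 5, position b & 31. Positions are
// 0-based gene indices assigned by the GeneUniverse; bits at positions >= U
// are never set because callers only pass positions < U.

// [[Rcpp::export]]
IntegerVector bs_from_positions(const IntegerVector& pos0, const int n_words) {
  IntegerVector out(n_words); // zero-initialised
  uint32_t* w = reinterpret_cast<uint32_t*>(INTEGER(out));
  const int n = pos0.size();
  for (int i = 0; i < n; ++i) {
    const int b = pos0[i];
    w[b >> 5] |= (1u << (b & 31));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector bs_or(const IntegerVector& a, const IntegerVector& b) {
  const int n = a.size();
  IntegerVector out(n);
  const uint32_t* wa = reinterpret_cast<const uint32_t*>(INTEGER(a));
  const uint32_t* wb = reinterpret_cast<const uint32_t*>(INTEGER(b));
  uint32_t* wo = reinterpret_cast<uint32_t*>(INTEGER(out));
  for (int i = 0; i < n; ++i) wo[i] = wa[i] | wb[i];
  return out;
}

// [[Rcpp::export]]
int bs_popcount(const IntegerVector& a) {
  const int n = a.size();
  const uint32_t* w = reinterpret_cast<const uint32_t*>(INTEGER(a));
  int c = 0;
  for (int i = 0; i < n; ++i) c += __builtin_popcount(w[i]);
  return c;
}

// [[Rcpp::export]]
int bs_and_popcount(const IntegerVector& a, const IntegerVector& b) {
  const int n = a.size();
  const uint32_t* wa = reinterpret_cast<const uint32_t*>(INTEGER(a));
  const uint32_t* wb = reinterpret_cast<const uint32_t*>(INTEGER(b));
  int c = 0;
  for (int i = 0; i < n; ++i) c += __builtin_popcount(wa[i] & wb[i]);
  return c;
}

// Bit-probing: for each category gene, test its bit in the group bitset and
// count the set bits. This is the size-only intersection.
// [[Rcpp::export]]
int bs_probe(const IntegerVector& a, const IntegerVector& pos0) {
  const uint32_t* w = reinterpret_cast<const uint32_t*>(INTEGER(a));
  const int m = pos0.size();
  int c = 0;
  for (int i = 0; i < m; ++i) {
    const int b = pos0[i];
    c += (w[b >> 5] >> (b & 31)) & 1u;
  }
  return c;
}

// Fold each group's member bitsets (columns of member_words, 1-based indices
// in `groups`) into a fresh all-zeros accumulator with bitwise-or.
// [[Rcpp::export]]
IntegerMatrix bs_pool_build(const IntegerMatrix& member_words, const List& groups) {
  const int n_words = member_words.nrow();
  const int n_groups = groups.size();
  IntegerMatrix pool(n_words, n_groups); // zero-initialised
  const uint32_t* src = reinterpret_cast<const uint32_t*>(INTEGER(member_words));
  uint32_t* dst = reinterpret_cast<uint32_t*>(INTEGER(pool));
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector idx = groups[g];
    uint32_t* acc = dst + (size_t)g * n_words;
    const int k = idx.size();
    for (int j = 0; j < k; ++j) {
      const uint32_t* col = src + (size_t)(idx[j] - 1) * n_words;
      for (int wi = 0; wi < n_words; ++wi) acc[wi] |= col[wi];
    }
  }
  return pool;
}

// Bit-probe one category against every pooled group bitset.
// [[Rcpp::export]]
IntegerVector bs_pool_probe(const IntegerMatrix& pool, const IntegerVector& pos0) {
  const int n_words = pool.nrow();
  const int n_groups = pool.ncol();
  const int m = pos0.size();
  IntegerVector out(n_groups);
  const uint32_t* w = reinterpret_cast<const uint32_t*>(INTEGER(pool));
  for (int g = 0; g < n_groups; ++g) {
    const uint32_t* col = w + (size_t)g * n_words;
    int c = 0;
    for (int i = 0; i < m; ++i) {
      const int b = pos0[i];
      c += (col[b >> 5] >> (b & 31)) & 1u;
    }
    out[g] = c;
  }
  return out;
}

// Decode set bits back to 0-based positions (R-side bit arithmetic cannot be
// used: a word whose pattern equals INT_MIN is R's NA_integer_).
// [[Rcpp::export]]
IntegerVector bs_positions(const IntegerVector& a) {
  const int n = a.size();
  const uint32_t* w = reinterpret_cast<const uint32_t*>(INTEGER(a));
  std::vector<int> pos;
  for (int i = 0; i < n; ++i) {
    uint32_t word = w[i];
    while (word) {
      const int b = __builtin_ctz(word);
      pos.push_back(i * 32 + b);
      word &= word - 1;
    }
  }
  return wrap(pos);
}
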