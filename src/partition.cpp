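#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <algorithm>
using namespace Rcpp;

// k-mer counting over quality lines.  Keys are the raw k bytes; for k <= 8
// they are packed into a uint64 to keep the hash map compact on large
// samples, otherwise std::string keys are used.

typedef std::unordered_map<uint64_t, double> U64Map;
typedef std::unordered_map<std::string, double> StrMap;

static inline uint64_t pack_key(const unsigned char* p, int k) {
  uint64_t key = 0;
  for (int j = 0; j < k; ++j) key = (key << 8) | p[j];
  return key;
}

// Count all overlapping k-mers of `lines`; return the distinct k-mers
// (lexicographically sorted), their counts, the total count, and the
// maximum raw line weight over the same lines (the normaliser w_max).
// [[Rcpp::export]]
List cpp_kmer_model(CharacterVector lines, int k) {
  if (k < 1) stop("k must be >= 1");
  R_xlen_t nl = lines.size();
  bool small_k = (k <= 8);
  U64Map m64;
  StrMap mstr;
  double total = 0.0;

  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    for (int i = 0; i + k <= n; ++i) {
      if (small_k) m64[pack_key(p + i, k)] += 1.0;
      else mstr[std::string((const char*)(p + i), (size_t)k)] += 1.0;
      total += 1.0;
    }
  }

  // materialise sorted k-mer strings and weights
  size_t nk = small_k ? m64.size() : mstr.size();
  std::vector<std::string> keys;
  keys.reserve(nk);
  if (small_k) {
    for (U64Map::const_iterator it = m64.begin(); it != m64.end(); ++it) {
      std::string s((size_t)k, '\0');
      uint64_t key = it->first;
      for (int j = k - 1; j >= 0; --j) { s[j] = (char)(key & 0xFF); key >>= 8; }
      keys.push_back(s);
    }
  } else {
    for (StrMap::const_iterator it = mstr.begin(); it != mstr.end(); ++it)
      keys.push_back(it->first);
  }
  std::sort(keys.begin(), keys.end());

  CharacterVector kmers(nk);
  NumericVector weights(nk);
  for (size_t i = 0; i < nk; ++i) {
    SET_STRING_ELT(kmers, (R_xlen_t)i, Rf_mkCharLen(keys[i].data(), (int)keys[i].size()));
    double cnt = small_k ? m64[pack_key((const unsigned char*)keys[i].data(), k)]
                         : mstr[keys[i]];
    weights[(R_xlen_t)i] = (total > 0) ? cnt / total : 0.0;
  }

  // raw line weights of the sample itself -> w_max
  double w_max = 0.0;
  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    int nk_line = n - k + 1;
    if (nk_line <= 0) continue;
    double sum = 0.0;
    for (int i = 0; i < nk_line; ++i) {
      double cnt = 0.0;
      if (small_k) {
        U64Map::const_iterator it = m64.find(pack_key(p + i, k));
        if (it != m64.end()) cnt = it->second;
      } else {
        StrMap::const_iterator it = mstr.find(std::string((const char*)(p + i), (size_t)k));
        if (it != mstr.end()) cnt = it->second;
      }
      sum += (total > 0) ? cnt / total : 0.0;
    }
    double w = sum / nk_line;
    if (w > w_max) w_max = w;
  }

  return List::create(_["kmers"] = kmers,
                      _["weights"] = weights,
                      _["total"] = total,
                      _["w_max"] = w_max);
}

// Raw line weight of each line under a frozen k-mer weight model:
// (sum of the line's k-mer weights) / (number of k-mers in the line);
// unseen k-mers weigh 0, lines shorter than k weigh 0.
// [[Rcpp::export]]
NumericVector cpp_line_weights(CharacterVector lines, CharacterVector kmers,
                               NumericVector weights, int k) {
  if (k < 1) stop("k must be >= 1");
  if (kmers.size() != weights.size()) stop("kmers/weights length mismatch");
  bool small_k = (k <= 8);
  U64Map m64;
  StrMap mstr;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP s = STRING_ELT(kmers, i);
    if (LENGTH(s) != k) stop("k-mer of length %d does not match k = %d", LENGTH(s), k);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    if (small_k) m64[pack_key(p, k)] = weights[i];
    else mstr[std::string((const char*)p, (size_t)k)] = weights[i];
  }
  R_xlen_t nl = lines.size();
  NumericVector out(nl);
  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    int nk_line = n - k + 1;
    if (nk_line <= 0) { out[li] = 0.0; continue; }
    double sum = 0.0;
    for (int i = 0; i < nk_line; ++i) {
      if (small_k) {
        U64Map::const_iterator it = m64.find(pack_key(p + i, k));
        if (it != m64.end()) sum += it->second;
      } else {
        StrMap::const_iterator it = mstr.find(std::string((const char*)(p + i), (size_t)k));
        if (it != mstr.end()) sum += it->second;
      }
    }
    out[li] = sum / nk_line;
  }
  return out;
}

// Occurrence counts of every byte value 0..255 over all lines.
// [[Rcpp::export]]
NumericVector cpp_byte_counts(CharacterVector lines) {
  NumericVector counts(256);
  R_xlen_t nl = lines.size();
  for (R_xlen_t li = 0; li < nl; ++li) {
    SEXP s = STRING_ELT(lines, li);
    const unsigned char* p = (const unsigned char*)CHAR(s);
    int n = LENGTH(s);
    for (int i = 0; i < n; ++i) counts[p[i]] += 1.0;
  }
  return counts;
}
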