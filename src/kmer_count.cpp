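#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else breaks the window.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return r;
}

static std::string decode_kmer(uint64_t x, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[x & 3];
    x >>= 2;
  }
  return s;
}

// Count all length-k windows over {A,C,G,T} in a set of reads; windows
// containing any other symbol are skipped. With canonical=true a k-mer and its
// reverse complement share the lexicographically smaller key.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector reads, int k, bool canonical) {
  if (k < 1 || k > 31)
    stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t val = 0;
    int run = 0; // length of current valid run ending here
    for (const char *p = s; *p; ++p) {
      int code = base_code(*p);
      if (code < 0) {
        run = 0;
        val = 0;
        continue;
      }
      val = ((val << 2) | (uint64_t)code) & mask;
      if (++run >= k) {
        uint64_t key = val;
        if (canonical) {
          uint64_t rc = revcomp_code(val, k);
          if (rc < key) key = rc;
        }
        ++counts[key];
      }
    }
  }
  std::vector<std::pair<uint64_t, int> > items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  IntegerVector out(items.size());
  CharacterVector nm(items.size());
  for (size_t i = 0; i < items.size(); ++i) {
    out[i] = items[i].second;
    nm[i] = decode_kmer(items[i].first, k);
  }
  out.attr("names") = nm;
  return out;
}

// Brute-force count of valid (all-ACGT) length-k windows, for bookkeeping.
// [[Rcpp::export]]
double cpp_total_windows(CharacterVector reads, int k) {
  double total = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int run = 0;
    for (const char *p = s; *p; ++p) {
      if (base_code(*p) < 0) run = 0;
      else if (++run >= k) ++total;
    }
  }
  return total;
}
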