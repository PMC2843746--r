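#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 marks anything outside A/C/G/T (ambiguity codes, N).
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string decode_kmer(uint32_t code, int k) {
  static const char bases[] = "ACGT";
  std::string w(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    w[i] = bases[code & 3u];
    code >>= 2;
  }
  return w;
}

// Tally every overlapping ambiguity-free window of length k on the given
// strand. Only observed words are returned (the 4^k table is never built,
// which keeps k = 13, 14 tractable). usable = number of tallied windows.
// [[Rcpp::export(name = ".kmer_count_cpp")]]
List kmer_count_cpp(std::string seq, int k) {
  if (k < 1 || k > 15)
    stop("k must be between 1 and 15");
  const int n = (int) seq.size();
  std::unordered_map<uint32_t, int> tab;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t code = 0;
  int run = 0;        // length of current ambiguity-free suffix
  long long usable = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) {
      run = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint32_t) b) & mask;
    if (++run >= k) {
      ++tab[code];
      ++usable;
    }
  }
  const int m = (int) tab.size();
  CharacterVector words(m);
  IntegerVector counts(m);
  int j = 0;
  for (std::unordered_map<uint32_t, int>::const_iterator it = tab.begin();
       it != tab.end(); ++it, ++j) {
    words[j] = decode_kmer(it->first, k);
    counts[j] = it->second;
  }
  return List::create(_["word"] = words, _["count"] = counts,
                      _["usable"] = (double) usable);
}
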