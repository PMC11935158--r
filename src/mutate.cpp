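#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Per-base iid substitution / insertion / deletion channel. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double sub_rate,
                                 double ins_rate, double del_rate) {
  RNGScope scope;
  const char bases[] = "ACGT";
  const int n = seqs.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = std::string(seqs[r]);
    std::string o;
    o.reserve(s.size() + 8);
    for (size_t i = 0; i <= s.size(); ++i) {
      if (ins_rate > 0 && unif_rand() < ins_rate)
        o.push_back(bases[(int)(unif_rand() * 4) & 3]);
      if (i == s.size()) break;
      if (del_rate > 0 && unif_rand() < del_rate) continue;
      char c = s[i];
      if (sub_rate > 0 && unif_rand() < sub_rate) {
        int cur = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : 3;
        int shift = 1 + ((int)(unif_rand() * 3) % 3);
        c = bases[(cur + shift) & 3];
      }
      o.push_back(c);
    }
    out[r] = o;
  }
  return out;
}
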