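#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <map>
#include <algorithm>
using namespace Rcpp;

static const int BIG = 1 << 28;

// Banded global alignment of member against template with traceback.
// Fills, for each template position, a vote for {A,C,G,T,-} and, for each
// junction (before template position t, 0..T), the inserted string.
static bool align_and_vote(const std::string& tpl, const std::string& mem, int band,
                           std::vector<std::array<int, 5>>& subs,
                           std::vector<std::map<std::string, int>>& ins) {
  const int T = tpl.size(), M = mem.size();
  if (std::abs(T - M) > band) return false;
  const int w = 2 * band + 1;
  // dp[i][j] over template i (rows), member j (cols), banded on j - i
  std::vector<int> dp((T + 1) * w, BIG);
  auto at = [&](int i, int j) -> int& { return dp[i * w + (j - i + band)]; };
  for (int j = 0; j <= std::min(M, band); ++j) at(0, j) = j;
  for (int i = 1; i <= T; ++i) {
    int lo = std::max(0, i - band), hi = std::min(M, i + band);
    for (int j = lo; j <= hi; ++j) {
      int best = BIG;
      if (j > 0 && j - 1 >= i - 1 - band && j - 1 <= i - 1 + band && at(i - 1, j - 1) < BIG)
        best = at(i - 1, j - 1) + (tpl[i - 1] != mem[j - 1]);
      if (j >= i - 1 - band && j <= i - 1 + band && at(i - 1, j) < BIG)
        best = std::min(best, at(i - 1, j) + 1);  // deletion in member
      if (j > 0 && j - 1 >= i - band && at(i, j - 1) < BIG)
        best = std::min(best, at(i, j - 1) + 1);  // insertion in member
      at(i, j) = best;
    }
  }
  if (at(T, M) >= BIG) return false;
  // traceback from (T, M)
  int i = T, j = M;
  std::string pending;  // reversed insertion run
  auto code = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
    return 0;
  };
  auto flush_ins = [&](int junction) {
    std::reverse(pending.begin(), pending.end());
    ins[junction][pending] += 1;
    pending.clear();
  };
  while (i > 0 || j > 0) {
    int cur = at(i, j);
    if (i > 0 && j > 0 && j - 1 >= i - 1 - band && j - 1 <= i - 1 + band &&
        at(i - 1, j - 1) < BIG && at(i - 1, j - 1) + (tpl[i - 1] != mem[j - 1]) == cur) {
      flush_ins(i);
      subs[i - 1][code(mem[j - 1])] += 1;
      --i; --j;
    } else if (i > 0 && j >= i - 1 - band && j <= i - 1 + band && at(i - 1, j) < BIG &&
               at(i - 1, j) + 1 == cur) {
      flush_ins(i);
      subs[i - 1][4] += 1;  // member deleted this template base
      --i;
    } else {
      pending.push_back(mem[j - 1]);
      --j;
    }
  }
  flush_ins(0);
  return true;
}

// One round of positional-majority consensus over cluster members.
// [[Rcpp::export]]
std::string cpp_consensus_round(std::string tpl, CharacterVector members, int band) {
  const int T = tpl.size();
  std::vector<std::array<int, 5>> subs(T, {0, 0, 0, 0, 0});
  std::vector<std::map<std::string, int>> ins(T + 1);
  int used = 0;
  for (int k = 0; k < members.size(); ++k) {
    std::string mem = std::string(members[k]);
    if (align_and_vote(tpl, mem, band, subs, ins)) ++used;
  }
  if (used == 0) return tpl;
  const char bases[] = "ACGT";
  std::string out;
  out.reserve(T + 8);
  auto emit_ins = [&](int junction) {
    // majority inserted string (empty string counts as a vote against)
    int best = 0; std::string bests;
    int total = 0;
    for (auto& kv : ins[junction]) total += kv.second;
    int empty = used - total;  // members with no recorded event still vote ""
    // members aligning through junction always flush (possibly empty) — total==used
    (void)empty;
    for (auto& kv : ins[junction]) {
      if (kv.first.empty()) continue;
      if (kv.second > best || (kv.second == best && kv.first < bests)) {
        best = kv.second; bests = kv.first;
      }
    }
    // Insertion evidence leaks into neighbouring substitution columns when
    // members carry extra noise near the junction, so a robust plurality
    // (>1/3 of members) is required rather than an absolute majority; noise
    // pileup at homopolymer junctions stays below ~10%.
    if (!bests.empty() && best * 3 > used) out += bests;
  };
  for (int i = 0; i < T; ++i) {
    emit_ins(i);
    int best = 0, barg = -1;
    for (int b = 0; b < 5; ++b)
      if (subs[i][b] > best) { best = subs[i][b]; barg = b; }
    if (barg >= 0 && barg < 4) out.push_back(bases[barg]);
    else if (barg == -1) out.push_back(tpl[i]);  // no coverage: keep template
    // barg == 4: majority deletion, emit nothing
  }
  emit_ins(T);
  return out;
}
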