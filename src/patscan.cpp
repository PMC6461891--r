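#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// PatScan-style degenerate pattern search with independent budgets for
// mismatches, insertions (extra subject bases) and deletions (skipped
// pattern bases).
//
// Subject and pattern arrive as integer nucleotide bitmasks
// (A=1, C=2, G=4, U=8; IUPAC letters are unions; subject N is 0 so it
// never satisfies a pattern class and always costs a mismatch, except
// against pattern N which is mask 15 -- still 0 overlap, so N in the
// subject is uniformly a mismatch; this is the documented convention).
//
// For one start position the DP tracks, per (pattern consumed i, subject
// consumed j), the set of reachable budget triples (mm, ins, del) as a
// 64-bit mask over a mixed-radix index. Budget products above 64 states
// are rejected by the R wrapper. Insertions are internal only (0 < i < m),
// so matches are not redundant shifts of one another.

// [[Rcpp::export(name = ".patscan_core")]]
IntegerMatrix patscan_core(IntegerVector subj, IntegerVector pat,
                           int max_mm, int max_ins, int max_del) {
  const int n = subj.size(), m = pat.size();
  const int sd = 1;                      // del stride
  const int si = max_del + 1;            // ins stride
  const int sm = (max_ins + 1) * (max_del + 1); // mm stride
  const int nstates = (max_mm + 1) * sm;
  if (nstates > 64) stop("budget state space too large (>64)");

  // masks of states allowed to take one more mm / ins / del
  uint64_t inc_mm = 0, inc_ins = 0, inc_del = 0;
  for (int mm = 0; mm <= max_mm; ++mm)
    for (int in = 0; in <= max_ins; ++in)
      for (int de = 0; de <= max_del; ++de) {
        uint64_t bit = 1ULL << (mm * sm + in * si + de * sd);
        if (mm < max_mm) inc_mm |= bit;
        if (in < max_ins) inc_ins |= bit;
        if (de < max_del) inc_del |= bit;
      }

  const int jmax = m + max_ins;
  std::vector<uint64_t> cur(jmax + 1), nxt(jmax + 1);

  std::vector<int> r_start, r_end, r_mm, r_ins, r_del;

  for (int s = 0; s < n; ++s) {
    // cur[j] holds reachable states at (i, j)
    std::fill(cur.begin(), cur.end(), 0ULL);
    cur[0] = 1ULL; // (mm,ins,del) = (0,0,0)
    // final-row accumulation
    uint64_t bestSeen = 0;
    int bestCost = INT_MAX, bestIndel = INT_MAX, bestEnd = -1;
    int bestMM = 0, bestIns = 0, bestDel = 0;

    for (int i = 0; i < m; ++i) {
      std::fill(nxt.begin(), nxt.end(), 0ULL);
      const int pm = pat[i];
      for (int j = 0; j <= jmax; ++j) {
        uint64_t st = cur[j];
        if (!st) continue;
        // insertion: consume subject base, stay at pattern i (internal only)
        if (i > 0 && j < jmax && s + j < n)
          cur[j + 1] |= (st & inc_ins) << si;
        st = cur[j]; // may have been extended by an earlier insertion
        // deletion: skip pattern char
        nxt[j] |= (st & inc_del) << sd;
        // match / mismatch: consume one subject base
        if (j < jmax && s + j < n) {
          bool compat = (pm & subj[s + j]) != 0;
          if (compat) nxt[j + 1] |= st;
          else        nxt[j + 1] |= (st & inc_mm) << sm;
        }
      }
      std::swap(cur, nxt);
    }

    // cur now holds states at i = m; pick best (cost, indel, leftmost end)
    for (int j = 0; j <= jmax; ++j) {
      uint64_t st = cur[j];
      if (!st) continue;
      for (int b = 0; b < nstates; ++b) {
        if (!(st & (1ULL << b))) continue;
        int mm = b / sm, in = (b % sm) / si, de = b % si;
        int cost = mm + in + de, indel = in + de, end = s + j;
        if (cost < bestCost ||
            (cost == bestCost && (indel < bestIndel ||
             (indel == bestIndel && end < bestEnd)))) {
          bestCost = cost; bestIndel = indel; bestEnd = end;
          bestMM = mm; bestIns = in; bestDel = de; bestSeen = 1;
        }
      }
    }
    if (bestSeen && bestEnd > s) { // zero-length matches excluded
      r_start.push_back(s); r_end.push_back(bestEnd);
      r_mm.push_back(bestMM); r_ins.push_back(bestIns); r_del.push_back(bestDel);
    }
  }

  IntegerMatrix out(r_start.size(), 5);
  for (size_t k = 0; k < r_start.size(); ++k) {
    out(k, 0) = r_start[k]; out(k, 1) = r_end[k];
    out(k, 2) = r_mm[k]; out(k, 3) = r_ins[k]; out(k, 4) = r_del[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "mismatches",
                                          "insertions", "deletions");
  return out;
}
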