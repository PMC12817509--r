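#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <map>
#include <string>
#include <vector>
#include <cctype>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
static inline int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': case 'U': return 8;
  case 'R': return 1 | 4;
  case 'Y': return 2 | 8;
  case 'S': return 2 | 4;
  case 'W': return 1 | 8;
  case 'K': return 4 | 8;
  case 'M': return 1 | 2;
  case 'B': return 2 | 4 | 8;
  case 'D': return 1 | 4 | 8;
  case 'H': return 1 | 2 | 8;
  case 'V': return 1 | 2 | 4;
  case 'N': return 1 | 2 | 4 | 8;
  default:  return 0;
  }
}

static inline bool iupac_match(char a, char b) {
  return (iupac_mask(a) & iupac_mask(b)) != 0;
}

// Semi-global alignment of a (short, possibly degenerate) primer against a
// read: the primer aligns end to end, the read contributes free ends.
// Returns 0-based half-open read coordinates of the best placement, the
// number of primer positions matched (IUPAC-aware) and the raw score.
// [[Rcpp::export(name = ".primer_align_cpp")]]
List primer_align_cpp(std::string subject, std::string primer,
                      int match = 2, int mismatch = -2, int gap = -3) {
  const int m = primer.size(), n = subject.size();
  if (m == 0 || n == 0 || m > n)
    return List::create(_["start"] = -1, _["end"] = -1,
                        _["matches"] = 0, _["score"] = NA_INTEGER);
  // H[i][j]: best score of primer[0..i) against a suffix of subject[0..j).
  std::vector<int> prev(n + 1), cur(n + 1);
  // Traceback: 0 = stop (free start), 1 = diag, 2 = up (gap in subject),
  // 3 = left (gap in primer).
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0);
  for (int j = 0; j <= n; ++j) prev[j] = 0;   // free leading read bases
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    tb[i * (n + 1)] = 2;
    for (int j = 1; j <= n; ++j) {
      const int s = iupac_match(primer[i - 1], subject[j - 1]) ? match : mismatch;
      int best = prev[j - 1] + s;
      unsigned char dir = 1;
      if (prev[j] + gap > best) { best = prev[j] + gap; dir = 2; }
      if (cur[j - 1] + gap > best) { best = cur[j - 1] + gap; dir = 3; }
      cur[j] = best;
      tb[i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // Best end anywhere on the last primer row (free trailing read bases).
  int best_j = 0, best_score = prev[0];
  for (int j = 1; j <= n; ++j)
    if (prev[j] > best_score) { best_score = prev[j]; best_j = j; }
  // Traceback (recompute directions are already stored).
  int i = m, j = best_j, matches = 0;
  while (i > 0) {
    unsigned char dir = tb[i * (n + 1) + j];
    if (dir == 1) {
      if (iupac_match(primer[i - 1], subject[j - 1])) ++matches;
      --i; --j;
    } else if (dir == 2) {
      --i;
    } else { // dir == 3
      --j;
    }
  }
  return List::create(_["start"] = j, _["end"] = best_j,
                      _["matches"] = matches, _["score"] = best_score);
}

// Banded overlap (free-end-gap) alignment of `query` against `ref`.
// Band is applied to the offset j - i and widened by the length difference.
// Returns per-ref-position operations for pileup use:
//   ops:  integer vector, length |ref|; -1 no coverage, 0..3 = A,C,G,T read
//         base aligned (match or substitution), 4 = deletion in read
//   ins:  insertion strings keyed by the 0-based ref position they precede
// score/matches/aln_len summarise the alignment.
struct OvlResult {
  std::vector<int> ops;
  std::map<int, std::string> ins;
  int score = 0, matches = 0, aln_len = 0;
  bool ok = false;
};

static inline int base_code(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -2; // ambiguous read base: treated as mismatch to all
  }
}

static OvlResult overlap_align(const std::string& ref, const std::string& query,
                               int band, int match, int mismatch, int gap) {
  OvlResult res;
  const int m = ref.size(), n = query.size();
  res.ops.assign(m, -1);
  if (m == 0 || n == 0) return res;
  const int lo_off = std::min(0, n - m) - band;
  const int hi_off = std::max(0, n - m) + band;
  const int W = hi_off - lo_off + 1;
  const int NEG = INT_MIN / 4;
  // cell (i, j) stored at row i, column j - i - lo_off
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<unsigned char> tb(static_cast<size_t>(m + 1) * W, 0);
  auto col = [&](int i, int j) { return j - i - lo_off; };
  for (int j = 0; j <= n; ++j) {
    int c = col(0, j);
    if (c >= 0 && c < W) { prev[c] = 0; tb[c] = 0; } // free leading query gap
  }
  int bi = -1, bj = -1, best = NEG;
  { // path may end with query exhausted at any ref row (free trailing ref)
    const int c0 = col(0, n);
    if (c0 >= 0 && c0 < W && prev[c0] > best) { best = prev[c0]; bi = 0; bj = n; }
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jlo = std::max(0, i + lo_off), jhi = std::min(n, i + hi_off);
    for (int j = jlo; j <= jhi; ++j) {
      const int c = col(i, j);
      int best = NEG; unsigned char dir = 0;
      if (j == 0) { best = 0; dir = 4; } // free leading ref gap
      if (j > 0) {
        const int cd = col(i - 1, j - 1);
        if (cd >= 0 && cd < W && prev[cd] > NEG) {
          int bq = base_code(query[j - 1]);
          int s = (bq >= 0 && std::toupper((unsigned char)ref[i - 1]) == "ACGT"[bq])
                    ? match : mismatch;
          if (prev[cd] + s > best) { best = prev[cd] + s; dir = 1; }
        }
      }
      { // gap in query (ref base deleted)
        const int cu = col(i - 1, j);
        if (cu >= 0 && cu < W && prev[cu] > NEG && prev[cu] + gap > best) {
          best = prev[cu] + gap; dir = 2;
        }
      }
      if (j > 0) { // gap in ref (insertion in query)
        const int cl = col(i, j - 1);
        if (cl >= 0 && cl < W && cur[cl] > NEG && cur[cl] + gap > best) {
          best = cur[cl] + gap; dir = 3;
        }
      }
      cur[c] = best;
      tb[static_cast<size_t>(i) * W + c] = dir;
    }
    { // candidate end with the query fully consumed at this ref row
      const int cn = col(i, n);
      if (cn >= 0 && cn < W && cur[cn] > best) { best = cur[cn]; bi = i; bj = n; }
    }
    std::swap(prev, cur);
  }
  // prev now holds row m: candidate ends with the ref fully consumed.
  for (int j = std::max(0, m + lo_off); j <= std::min(n, m + hi_off); ++j) {
    const int c = col(m, j);
    if (c >= 0 && c < W && prev[c] > best) { best = prev[c]; bi = m; bj = j; }
  }
  if (bj < 0) return res;
  res.score = best;
  int i = bi, j = bj;
  std::vector<std::pair<int,int>> path; // (ref_pos or -1, op)
  while (i > 0 || j > 0) {
    const int c = col(i, j);
    if (c < 0 || c >= W) break;
    unsigned char dir = tb[static_cast<size_t>(i) * W + c];
    if (dir == 0 || dir == 4) break; // free start reached
    if (dir == 1) {
      int bq = base_code(query[j - 1]);
      res.ops[i - 1] = (bq >= 0) ? bq : 5; // 5 = ambiguous, ignore in pileup
      if (bq >= 0 && std::toupper((unsigned char)ref[i - 1]) == "ACGT"[bq])
        ++res.matches;
      ++res.aln_len;
      --i; --j;
    } else if (dir == 2) {
      res.ops[i - 1] = 4; ++res.aln_len;
      --i;
    } else { // insertion before ref position i (0-based)
      res.ins[i] = query[j - 1] + res.ins[i];
      ++res.aln_len;
      --j;
    }
  }
  res.ok = true;
  return res;
}

// [[Rcpp::export(name = ".overlap_identity_cpp")]]
List overlap_identity_cpp(std::string ref, std::string query, int band = 100,
                          int match = 2, int mismatch = -3, int gap = -4) {
  OvlResult r = overlap_align(ref, query, band, match, mismatch, gap);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["matches"] = r.matches, _["aln_len"] = r.aln_len);
}

// One round of pileup-majority polishing: align every read to the draft with
// banded overlap alignment, tally per-position base/deletion operations and
// per-junction insertions, and rewrite the draft by weighted majority.
// Ties are broken toward the draft base; insertions require a strict
// majority of the reads covering the junction.
// [[Rcpp::export(name = ".polish_round_cpp")]]
List polish_round_cpp(std::string draft, CharacterVector reads, int band = 80,
                      int match = 2, int mismatch = -3, int gap = -4) {
  const int L = draft.size();
  std::vector<std::array<int, 5>> counts(L, {0, 0, 0, 0, 0});
  std::vector<int> cov(L, 0);
  std::vector<int> junction_cov(L + 1, 0);
  std::vector<std::map<std::string, int>> ins(L + 1);
  int n_aligned = 0;
  for (int k = 0; k < reads.size(); ++k) {
    std::string q = as<std::string>(reads[k]);
    int b = band + std::abs((int)q.size() - L) / 4;
    OvlResult r = overlap_align(draft, q, b, match, mismatch, gap);
    if (!r.ok || r.aln_len == 0) continue;
    // Require a minimally sane alignment before counting it.
    if (r.matches * 2 < (int)std::min(q.size(), (size_t)L)) continue;
    ++n_aligned;
    int first = -1, last = -1;
    for (int i = 0; i < L; ++i) {
      if (r.ops[i] >= 0) {
        if (first < 0) first = i;
        last = i;
      }
    }
    for (int i = 0; i < L; ++i) {
      if (r.ops[i] >= 0 && r.ops[i] <= 4) {
        counts[i][r.ops[i]] += 1;
        ++cov[i];
      } else if (r.ops[i] == 5) {
        ++cov[i];
      }
    }
    if (first >= 0)
      for (int i = first + 1; i <= last; ++i) ++junction_cov[i];
    for (auto& kv : r.ins)
      if (kv.first > first && kv.first <= last) ins[kv.first][kv.second] += 1;
  }
  std::string out;
  out.reserve(L + 16);
  const char* B = "ACGT";
  for (int i = 0; i <= L; ++i) {
    if (i > 0 && i < L + 1) {} // noop
    // insertions before position i
    if (!ins[i].empty() && junction_cov[i] > 0) {
      int best_c = 0; std::string best_s;
      for (auto& kv : ins[i])
        if (kv.second > best_c) { best_c = kv.second; best_s = kv.first; }
      if (2 * best_c > junction_cov[i]) out += best_s;
    }
    if (i == L) break;
    if (cov[i] == 0) { out += draft[i]; continue; }
    int draft_code = base_code(draft[i]);
    int best_op = (draft_code >= 0) ? draft_code : 0;
    int best_n = (draft_code >= 0) ? counts[i][draft_code] : -1;
    for (int op = 0; op < 5; ++op)
      if (counts[i][op] > best_n) { best_n = counts[i][op]; best_op = op; }
    if (best_op < 4) out += B[best_op];
    // best_op == 4: deletion, emit nothing
  }
  return List::create(_["seq"] = out, _["n_aligned"] = n_aligned);
}
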