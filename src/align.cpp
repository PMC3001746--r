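#include "poshmap.h"
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---- k-mer level alignment -------------------------------------------------
//
// Greedy run extension: matches are processed in (read_offset, window_offset)
// order; a match extends the best-scoring compatible live run, or starts a
// new run scored t*m.  The reward for an extension discounts sampled
// positions already paid for by the previous k-mer via ovl(d).

RunResult kmer_align_core(const std::vector<std::pair<int, int>> &mm,
                          const std::vector<int> &ovl, int t, int span,
                          double m, double g, int max_drift) {
  struct Run {
    double score;
    int last_ro, last_wo;
    int min_wo;
    std::vector<int> mem;
  };
  std::vector<Run> runs;
  for (int i = 0; i < (int)mm.size(); ++i) {
    int ro = mm[i].first, wo = mm[i].second;
    int diag = wo - ro;
    double best_score = 0.0;
    int best_run = -1;
    for (int r = 0; r < (int)runs.size(); ++r) {
      const Run &ru = runs[r];
      if (ro <= ru.last_ro || wo <= ru.last_wo) continue;
      int gap = std::abs(diag - (ru.last_wo - ru.last_ro));
      if (gap > max_drift) continue;
      int d = span - (ro - ru.last_ro);
      if (d < 0) d = 0;
      double ns = ru.score + (t - ovl[d]) * m - g * gap;
      if (best_run < 0 || ns > best_score) {
        best_score = ns;
        best_run = r;
      }
    }
    if (best_run >= 0) {
      Run &ru = runs[best_run];
      ru.score = best_score;
      ru.last_ro = ro;
      ru.last_wo = wo;
      ru.mem.push_back(i);
    } else {
      Run ru;
      ru.score = (double)t * m;
      ru.last_ro = ro;
      ru.last_wo = wo;
      ru.min_wo = wo;
      ru.mem.push_back(i);
      runs.push_back(std::move(ru));
    }
  }
  RunResult res;
  int best = -1;
  for (int r = 0; r < (int)runs.size(); ++r) {
    if (best < 0 || runs[r].score > res.score ||
        (runs[r].score == res.score && runs[r].min_wo < runs[best].min_wo)) {
      best = r;
      res.score = runs[r].score;
    }
  }
  if (best >= 0) res.members = runs[best].mem;
  else res.score = 0.0;
  return res;
}

// Affine bound on the basepair score of a run: reward for read positions
// covered by the union of its k-mer spans, minus affine charges for each
// diagonal shift within the run.
double skeleton_core(const std::vector<std::pair<int, int>> &mm, int span,
                     double match, double gap_open, double gap_extend) {
  if (mm.empty()) return 0.0;
  long covered = 0;
  long cur_end = -1;
  int n_shift = 0;
  long tot_gap = 0;
  for (size_t i = 0; i < mm.size(); ++i) {
    long s = mm[i].first, e = s + span;
    if (s >= cur_end) covered += e - s;
    else if (e > cur_end) covered += e - cur_end;
    if (e > cur_end) cur_end = e;
    if (i > 0) {
      int dd = (mm[i].second - mm[i].first) - (mm[i - 1].second - mm[i - 1].first);
      if (dd != 0) {
        ++n_shift;
        tot_gap += std::abs(dd);
      }
    }
  }
  return match * (double)covered - gap_open * n_shift - gap_extend * (double)tot_gap;
}

// ---- banded affine-gap local alignment -------------------------------------
//
// Three-state (M/D/I) local DP restricted to diagonals lo..hi (diag = j - i,
// ref index minus read index).  Penalties ma/mi/go/ge are magnitudes; a gap
// of length L costs go + ge * L.  In bisulfite mode read T vs ref C scores
// (and is reported in NM) as a match.  Tie-breaking is fixed: the best cell
// is the first maximal M cell in (i, j) scan order; within a cell the source
// preference is M > D > I > local start, and gap states prefer opening.

static const double NEG = -1e18;

AlnResult banded_core(const std::string &read, const std::string &ref, int lo,
                      int hi, double ma, double mi, double go, double ge,
                      bool bisulfite) {
  AlnResult res;
  int n = (int)read.size(), m = (int)ref.size();
  size_t sz = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<double> M(sz, NEG), D(sz, NEG), I(sz, NEG);
  std::vector<uint8_t> tM(sz, 0), tD(sz, 0), tI(sz, 0);
  auto ix = [m](int i, int j) { return (size_t)i * (size_t)(m + 1) + j; };
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + lo), jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      res.any_cell = true;
      size_t c = ix(i, j);
      char rb = read[i - 1], gb = ref[j - 1];
      bool is_match = (rb == gb && base_code(rb) >= 0) ||
                      (bisulfite && rb == 'T' && gb == 'C');
      double s = is_match ? ma : -mi;
      // M state: diagonal move, may start a fresh local alignment
      size_t d = ix(i - 1, j - 1);
      double pm = M[d], pd = D[d], pi = I[d];
      double bprev = 0.0;
      uint8_t src = 0;
      if (pm >= bprev) { bprev = pm; src = 1; }
      if (pd > bprev) { bprev = pd; src = 2; }
      if (pi > bprev) { bprev = pi; src = 3; }
      M[c] = s + bprev;
      tM[c] = src;
      // D state: consume ref (deletion from the read's perspective)
      size_t l = ix(i, j - 1);
      double open_d = (M[l] > NEG / 2) ? M[l] - go - ge : NEG;
      double ext_d = (D[l] > NEG / 2) ? D[l] - ge : NEG;
      if (open_d >= ext_d) { D[c] = open_d; tD[c] = 1; }
      else { D[c] = ext_d; tD[c] = 2; }
      // I state: consume read (insertion relative to the ref)
      size_t u = ix(i - 1, j);
      double open_i = (M[u] > NEG / 2) ? M[u] - go - ge : NEG;
      double ext_i = (I[u] > NEG / 2) ? I[u] - ge : NEG;
      if (open_i >= ext_i) { I[c] = open_i; tI[c] = 1; }
      else { I[c] = ext_i; tI[c] = 2; }
      if (M[c] > best) {
        best = M[c];
        bi = i;
        bj = j;
      }
    }
  }
  if (bi < 0) {  // no positive-scoring cell: empty alignment
    res.score = 0.0;
    return res;
  }
  res.score = best;
  // traceback
  std::string ops;
  int i = bi, j = bj, state = 1;
  while (true) {
    size_t c = ix(i, j);
    if (state == 1) {
      char rb = read[i - 1], gb = ref[j - 1];
      bool is_match = (rb == gb && base_code(rb) >= 0) ||
                      (bisulfite && rb == 'T' && gb == 'C');
      if (!is_match) ++res.nm;
      ops.push_back('M');
      uint8_t src = tM[c];
      --i; --j;
      if (src == 0) break;
      state = src;
    } else if (state == 2) {
      ops.push_back('D');
      ++res.nm;
      uint8_t src = tD[c];
      --j;
      state = (src == 1) ? 1 : 2;
    } else {
      ops.push_back('I');
      ++res.nm;
      uint8_t src = tI[c];
      --i;
      state = (src == 1) ? 1 : 2 + 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.read_start = i;
  res.ref_start = j;
  res.read_end = bi;
  res.ref_end = bj;
  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  res.cigar = cig;
  return res;
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export]]
List pm_kmer_align(IntegerVector read_offsets, IntegerVector window_offsets,
                   IntegerVector ovl, int t, int span, double m, double g,
                   int max_drift) {
  std::vector<std::pair<int, int>> mm(read_offsets.size());
  for (int i = 0; i < read_offsets.size(); ++i)
    mm[i] = {read_offsets[i], window_offsets[i]};
  std::sort(mm.begin(), mm.end());
  std::vector<int> ov = as<std::vector<int>>(ovl);
  RunResult r = kmer_align_core(mm, ov, t, span, m, g, max_drift);
  int k = (int)r.members.size();
  IntegerVector ro(k), wo(k);
  for (int i = 0; i < k; ++i) {
    ro[i] = mm[r.members[i]].first;
    wo[i] = mm[r.members[i]].second;
  }
  return List::create(_["score"] = r.score, _["read_offsets"] = ro,
                      _["window_offsets"] = wo);
}

// [[Rcpp::export]]
double pm_skeleton(IntegerVector read_offsets, IntegerVector window_offsets,
                   int span, double match, double gap_open,
                   double gap_extend) {
  std::vector<std::pair<int, int>> mm(read_offsets.size());
  for (int i = 0; i < read_offsets.size(); ++i)
    mm[i] = {read_offsets[i], window_offsets[i]};
  std::sort(mm.begin(), mm.end());
  return skeleton_core(mm, span, match, gap_open, gap_extend);
}

// [[Rcpp::export]]
List pm_banded_align(std::string read, std::string ref, int lo, int hi,
                     double match, double mismatch, double gap_open,
                     double gap_extend, bool bisulfite) {
  AlnResult a = banded_core(read, ref, lo, hi, match, mismatch, gap_open,
                            gap_extend, bisulfite);
  if (!a.any_cell)
    stop("band [%d, %d] excludes every cell of a %d x %d matrix", lo, hi,
         (int)read.size(), (int)ref.size());
  return List::create(
      _["score"] = a.score, _["cigar"] = a.cigar,
      _["read_start"] = a.read_start, _["read_end"] = a.read_end,
      _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end, _["nm"] = a.nm);
}
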