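#include "poshmap.h"
#include <algorithm>

using namespace Rcpp;

void expand_bisulfite_key(uint64_t key, int weight, int cap,
                          std::vector<uint64_t> &out) {
  out.clear();
  std::vector<int> tpos;  // bit positions (from low end) holding a T
  for (int i = 0; i < weight; ++i) {
    if (((key >> (2 * i)) & 3ULL) == 3ULL) tpos.push_back(i);
  }
  int nt = (int)tpos.size();
  if (nt > cap) return;  // pathological T-rich k-mer: contribute nothing
  size_t n = (size_t)1 << nt;
  out.reserve(n);
  for (size_t mask = 0; mask < n; ++mask) {
    uint64_t k = key;
    for (int b = 0; b < nt; ++b) {
      if (mask & ((size_t)1 << b)) {
        // flip this T (code 3) to C (code 1)
        k &= ~(2ULL << (2 * tpos[b]));
      }
    }
    out.push_back(k);
  }
}

static void index_one_read(MPIndex &idx, const std::string &seq, int read_i,
                           uint8_t rc, std::vector<uint64_t> &scratch) {
  int L = (int)seq.size();
  if (L < idx.span) return;
  std::vector<int> starts;
  for (int p = 0; p + idx.span <= L; p += idx.G) starts.push_back(p);
  int last = L - idx.span;
  if (starts.empty() || starts.back() != last) starts.push_back(last);
  for (int p : starts) {
    uint64_t key;
    if (!sample_key(seq, p, idx.offsets, idx.span, key)) continue;
    KEntry e;
    e.read = read_i;
    e.offset = p;
    e.rc = rc;
    if (idx.bisulfite) {
      expand_bisulfite_key(key, idx.weight, idx.expansion_cap, scratch);
      for (uint64_t k : scratch) idx.table[k].push_back(e);
    } else {
      idx.table[key].push_back(e);
    }
  }
}

void build_index_core(MPIndex &idx, const std::vector<std::string> &reads) {
  idx.n_reads = (int)reads.size();
  idx.read_len.resize(reads.size());
  idx.unmappable.assign(reads.size(), 0);
  std::vector<uint64_t> scratch;
  for (size_t i = 0; i < reads.size(); ++i) {
    idx.read_len[i] = (int)reads[i].size();
    if ((int)reads[i].size() < idx.span) {
      idx.unmappable[i] = 1;
      continue;
    }
    index_one_read(idx, reads[i], (int)i, 0, scratch);
    if (idx.include_rc) index_one_read(idx, revcomp(reads[i]), (int)i, 1, scratch);
  }
  if (idx.kept_fraction < 1.0) {
    // rank distinct keys by entry count (ascending), ties by key value, and
    // keep only the lowest-frequency kept_fraction of them
    std::vector<std::pair<size_t, uint64_t>> freq;
    freq.reserve(idx.table.size());
    size_t total = 0;
    for (auto &kv : idx.table) {
      freq.push_back({kv.second.size(), kv.first});
      total += kv.second.size();
    }
    std::sort(freq.begin(), freq.end());
    size_t n_keep =
        (size_t)std::floor(idx.kept_fraction * (double)freq.size() + 1e-9);
    // never split a frequency class: keys tied with the boundary frequency
    // are all retained, so equally common k-mers share one fate
    if (n_keep > 0 && n_keep < freq.size()) {
      size_t boundary = freq[n_keep - 1].first;
      while (n_keep < freq.size() && freq[n_keep].first == boundary) ++n_keep;
    }
    // only genuinely overrepresented keys are discardable: the filter is a
    // speed knob aimed at repetitive k-mers, so a key is never thrown away
    // unless its count exceeds both twice the mean entries-per-key and an
    // absolute floor (collating a handful of entries costs nothing)
    double over = std::max(10.0, 2.0 * (double)total / (double)freq.size());
    for (size_t i = n_keep; i < freq.size(); ++i)
      if ((double)freq[i].first > over) idx.table.erase(freq[i].second);
  }
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export]]
SEXP pm_build_index(CharacterVector reads, IntegerVector offsets, int span,
                    int G, bool bisulfite, bool include_rc,
                    double kept_fraction, int expansion_cap) {
  XPtr<MPIndex> xp(new MPIndex(), true);
  xp->offsets = as<std::vector<int>>(offsets);
  xp->span = span;
  xp->weight = (int)offsets.size();
  xp->G = G;
  xp->bisulfite = bisulfite;
  xp->include_rc = include_rc;
  xp->kept_fraction = kept_fraction;
  xp->expansion_cap = expansion_cap;
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);
  build_index_core(*xp, rd);
  return xp;
}

// [[Rcpp::export]]
DataFrame pm_index_lookup(SEXP xp_, std::string key) {
  XPtr<MPIndex> xp(xp_);
  uint64_t k = 0;
  if ((int)key.size() != xp->weight) {
    return DataFrame::create(_["read_id"] = IntegerVector(0),
                             _["offset"] = IntegerVector(0),
                             _["rc"] = LogicalVector(0));
  }
  for (char c : key) {
    int b = base_code(c);
    if (b < 0) stop("k-mer key contains a non-ACGT character");
    k = (k << 2) | (uint64_t)b;
  }
  auto it = xp->table.find(k);
  int n = (it == xp->table.end()) ? 0 : (int)it->second.size();
  IntegerVector read(n), off(n);
  LogicalVector rc(n);
  for (int i = 0; i < n; ++i) {
    read[i] = it->second[i].read + 1;  // 1-based for R
    off[i] = it->second[i].offset;
    rc[i] = it->second[i].rc != 0;
  }
  return DataFrame::create(_["read_id"] = read, _["offset"] = off, _["rc"] = rc);
}

// [[Rcpp::export]]
List pm_index_info(SEXP xp_) {
  XPtr<MPIndex> xp(xp_);
  size_t n_entries = 0;
  std::vector<uint64_t> keys;
  keys.reserve(xp->table.size());
  for (auto &kv : xp->table) {
    n_entries += kv.second.size();
    keys.push_back(kv.first);
  }
  std::sort(keys.begin(), keys.end());
  CharacterVector ks(keys.size());
  IntegerVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    ks[i] = key_to_string(keys[i], xp->weight);
    cnt[i] = (int)xp->table[keys[i]].size();
  }
  return List::create(_["n_entries"] = (double)n_entries,
                      _["n_keys"] = (double)keys.size(), _["key"] = ks,
                      _["count"] = cnt,
                      _["unmappable"] = LogicalVector(
                          xp->unmappable.begin(), xp->unmappable.end()));
}

// [[Rcpp::export]]
SEXP pm_sample_kmer(std::string seq, int pos, IntegerVector offsets, int span) {
  uint64_t key;
  std::vector<int> off = as<std::vector<int>>(offsets);
  if (!sample_key(seq, pos, off, span, key)) return R_NilValue;
  return wrap(key_to_string(key, (int)off.size()));
}

// [[Rcpp::export]]
CharacterVector pm_expand_bisulfite(std::string kmer, int cap) {
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) stop("k-mer contains a non-ACGT character");
    key = (key << 2) | (uint64_t)b;
  }
  std::vector<uint64_t> out;
  expand_bisulfite_key(key, (int)kmer.size(), cap, out);
  std::sort(out.begin(), out.end());
  CharacterVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i)
    res[i] = key_to_string(out[i], (int)kmer.size());
  return res;
}
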