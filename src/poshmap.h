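#ifndef POSHMAP_H
#define POSHMAP_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

// 2-bit base codes; anything outside upper-case ACGT is invalid (-1)
inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

inline char code_base(int c) { return "ACGT"[c]; }

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// Sample the gapped k-mer at `pos` of `seq`; returns false if out of bounds
// or a sampled base is not ACGT.  Key packs bases 2 bits each, first offset
// in the highest bits, so numeric order == lexicographic order of the string.
inline bool sample_key(const std::string &seq, long pos,
                       const std::vector<int> &offsets, int span,
                       uint64_t &key) {
  if (pos < 0 || pos + span > (long)seq.size()) return false;
  uint64_t k = 0;
  for (int off : offsets) {
    int c = base_code(seq[pos + off]);
    if (c < 0) return false;
    k = (k << 2) | (uint64_t)c;
  }
  key = k;
  return true;
}

inline std::string key_to_string(uint64_t key, int weight) {
  std::string s(weight, 'A');
  for (int i = weight - 1; i >= 0; --i) {
    s[i] = code_base((int)(key & 3ULL));
    key >>= 2;
  }
  return s;
}

struct KEntry {
  int32_t read;    // 0-based read index
  int32_t offset;  // 0-based sampling offset within the (oriented) read
  uint8_t rc;      // 1 if the entry comes from the reverse complement
};

struct MPIndex {
  std::unordered_map<uint64_t, std::vector<KEntry>> table;
  std::vector<int> offsets;
  int span = 0;
  int weight = 0;
  int G = 1;
  bool bisulfite = false;
  bool include_rc = false;
  double kept_fraction = 1.0;
  int expansion_cap = 10;
  int n_reads = 0;
  std::vector<int> read_len;
  std::vector<uint8_t> unmappable;
};

// Bisulfite k-mer space: every T may stand for a converted C, so each T is
// expanded to {T, C}.  Keys with more than `cap` Ts are skipped entirely.
void expand_bisulfite_key(uint64_t key, int weight, int cap,
                          std::vector<uint64_t> &out);

void build_index_core(MPIndex &idx, const std::vector<std::string> &reads);

struct RunResult {
  double score = 0.0;
  std::vector<int> members;  // indices into the (sorted) match vector
};

// Greedy run extension over matches sorted by (read_offset, window_offset).
RunResult kmer_align_core(const std::vector<std::pair<int, int>> &mm,
                          const std::vector<int> &ovl, int t, int span,
                          double m, double g, int max_drift);

double skeleton_core(const std::vector<std::pair<int, int>> &mm, int span,
                     double match, double gap_open, double gap_extend);

struct AlnResult {
  double score = 0.0;
  std::string cigar;       // M/I/D ops only (no clips)
  int read_start = 0, read_end = 0;  // 0-based half-open on the read
  int ref_start = 0, ref_end = 0;    // 0-based half-open on the ref segment
  int nm = 0;
  bool any_cell = false;   // band intersected the matrix at all
};

AlnResult banded_core(const std::string &read, const std::string &ref,
                      int lo, int hi, double ma, double mi, double go,
                      double ge, bool bisulfite);

#endif
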