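#include "poshmap.h"
#include <algorithm>
#include <cctype>
#include <map>
#include <tuple>

using namespace Rcpp;

// Candidate mapping buffer entry (window-deduplicated, pre select_best)
struct Cand {
  int read;        // 0-based
  int ref;         // 0-based index into the genome vector
  char strand;     // '+' or '-'
  long pos;        // 0-based leftmost position on the forward strand
  double score;    // banded DP score
  std::string cigar;  // M/I/D ops, forward-strand orientation, no clips
  int nm;
  int read_start, read_end;  // 0-based half-open on the emitted (oriented) SEQ
  double kscore, skeleton;
};

static std::string reverse_cigar(const std::string &cig) {
  // reverse the op order of an RLE cigar string
  std::vector<std::string> toks;
  size_t p = 0;
  while (p < cig.size()) {
    size_t q = p;
    while (q < cig.size() && isdigit(cig[q])) ++q;
    ++q;  // op char
    toks.push_back(cig.substr(p, q - p));
    p = q;
  }
  std::string out;
  for (auto it = toks.rbegin(); it != toks.rend(); ++it) out += *it;
  return out;
}

// [[Rcpp::export]]
List pm_map_reads(CharacterVector reads, CharacterVector genome,
                  IntegerVector pat_offsets, int span, int G, int W,
                  double kept_fraction, double candidate_fraction,
                  double km_m, double km_g, int max_drift, double bp_match,
                  double bp_mismatch, double bp_gap_open,
                  double bp_gap_extend, int band_pad, bool bisulfite,
                  int expansion_cap) {
  int n_reads = reads.size();
  std::vector<std::string> rd(n_reads), rd_rc(n_reads);
  for (int i = 0; i < n_reads; ++i) {
    rd[i] = as<std::string>(reads[i]);
    rd_rc[i] = revcomp(rd[i]);
  }

  MPIndex idx;
  idx.offsets = as<std::vector<int>>(pat_offsets);
  idx.span = span;
  idx.weight = (int)idx.offsets.size();
  idx.G = G;
  idx.bisulfite = bisulfite;
  idx.include_rc = !bisulfite;
  idx.kept_fraction = kept_fraction;
  idx.expansion_cap = expansion_cap;
  build_index_core(idx, rd);

  std::vector<int> ovl(span + 1, 0);
  for (int d = 0; d <= span; ++d) {
    int s = span - d;
    int cnt = 0;
    for (int a : idx.offsets)
      for (int b : idx.offsets)
        if (b + s == a) ++cnt;
    ovl[d] = cnt;
  }

  std::vector<double> bestK(n_reads, 0.0), bestS(n_reads, 0.0);
  std::map<std::tuple<int, int, char, long>, Cand> buffer;

  for (int ci = 0; ci < genome.size(); ++ci) {
    std::string fwd = as<std::string>(genome[ci]);
    long len = (long)fwd.size();
    int n_streams = bisulfite ? 2 : 1;
    for (int st = 0; st < n_streams; ++st) {
      bool rc_stream = (st == 1);
      std::string seq = rc_stream ? revcomp(fwd) : fwd;
      for (long wstart = 0; wstart < len; wstart += W) {
        if (wstart > 0 && len <= 2L * W) break;  // short sequence: one window
        long wlen = std::min((long)2 * W, len - wstart);
        if (wlen < span) continue;
        // gather matches per (read, orientation)
        std::map<int, std::vector<std::pair<int, int>>> groups;
        for (long p = 0; p + span <= wlen; ++p) {
          uint64_t key;
          if (!sample_key(seq, wstart + p, idx.offsets, span, key)) continue;
          auto it = idx.table.find(key);
          if (it == idx.table.end()) continue;
          for (const KEntry &e : it->second)
            groups[(e.read << 1) | e.rc].push_back({e.offset, (int)p});
        }
        for (auto &kv : groups) {
          int read_i = kv.first >> 1;
          bool rc_read = (kv.first & 1) != 0;
          auto &mm = kv.second;
          std::sort(mm.begin(), mm.end());
          RunResult run =
              kmer_align_core(mm, ovl, idx.weight, span, km_m, km_g, max_drift);
          double ks = run.score;
          bool pass1 = ks > candidate_fraction * bestK[read_i];
          if (ks > bestK[read_i]) bestK[read_i] = ks;
          if (!pass1 || run.members.empty()) continue;
          std::vector<std::pair<int, int>> rmm;
          rmm.reserve(run.members.size());
          for (int m : run.members) rmm.push_back(mm[m]);
          double skel = skeleton_core(rmm, span, bp_match, bp_gap_open,
                                      bp_gap_extend);
          bool pass2 = skel > candidate_fraction * bestS[read_i];
          if (skel > bestS[read_i]) bestS[read_i] = skel;
          if (!pass2) continue;
          // banded DP around the run's diagonal extent
          const std::string &rstr = rc_read ? rd_rc[read_i] : rd[read_i];
          int rlen = (int)rstr.size();
          int dmin = rmm[0].second - rmm[0].first, dmax = dmin;
          for (auto &m : rmm) {
            int d = m.second - m.first;
            if (d < dmin) dmin = d;
            if (d > dmax) dmax = d;
          }
          long seg_start = std::max(0L, (long)dmin - band_pad);
          long seg_end = std::min(wlen, (long)dmax + rlen + band_pad);
          if (seg_end <= seg_start) continue;
          std::string seg =
              seq.substr(wstart + seg_start, seg_end - seg_start);
          int lo = dmin - band_pad - (int)seg_start;
          int hi = dmax + band_pad - (int)seg_start;
          AlnResult a = banded_core(rstr, seg, lo, hi, bp_match, bp_mismatch,
                                    bp_gap_open, bp_gap_extend, bisulfite);
          if (a.score <= 0) continue;
          long stream_pos = wstart + seg_start + a.ref_start;
          long rcons = a.ref_end - a.ref_start;
          Cand c;
          c.read = read_i;
          c.ref = ci;
          c.score = a.score;
          c.nm = a.nm;
          c.kscore = ks;
          c.skeleton = skel;
          if (rc_stream) {
            // bisulfite reverse-strand: lift to forward coordinates
            c.strand = '-';
            c.pos = len - (stream_pos + rcons);
            c.cigar = reverse_cigar(a.cigar);
            c.read_start = rlen - a.read_end;
            c.read_end = rlen - a.read_start;
          } else {
            c.strand = rc_read ? '-' : '+';
            c.pos = stream_pos;
            c.cigar = a.cigar;
            c.read_start = a.read_start;
            c.read_end = a.read_end;
          }
          auto key = std::make_tuple(c.read, c.ref, c.strand, c.pos);
          auto it = buffer.find(key);
          if (it == buffer.end() || c.score > it->second.score)
            buffer[key] = c;
        }
      }
    }
  }

  int n = (int)buffer.size();
  IntegerVector read(n), refi(n), nm(n), rs(n), re(n);
  NumericVector pos(n), score(n), kscore(n), skel(n);
  CharacterVector strand(n), cigar(n);
  int i = 0;
  std::vector<const Cand *> ord;
  ord.reserve(n);
  for (auto &kv : buffer) ord.push_back(&kv.second);
  std::stable_sort(ord.begin(), ord.end(), [](const Cand *a, const Cand *b) {
    if (a->read != b->read) return a->read < b->read;
    if (a->ref != b->ref) return a->ref < b->ref;
    if (a->pos != b->pos) return a->pos < b->pos;
    return a->strand < b->strand;
  });
  for (const Cand *c : ord) {
    read[i] = c->read + 1;
    refi[i] = c->ref + 1;
    strand[i] = std::string(1, c->strand);
    pos[i] = (double)c->pos;
    score[i] = c->score;
    cigar[i] = c->cigar;
    nm[i] = c->nm;
    rs[i] = c->read_start;
    re[i] = c->read_end;
    kscore[i] = c->kscore;
    skel[i] = c->skeleton;
    ++i;
  }
  DataFrame cands = DataFrame::create(
      _["read_id"] = read, _["ref_id"] = refi, _["strand"] = strand,
      _["pos"] = pos, _["score"] = score, _["cigar"] = cigar, _["nm"] = nm,
      _["read_start"] = rs, _["read_end"] = re, _["kmer_score"] = kscore,
      _["skeleton"] = skel, _["stringsAsFactors"] = false);
  return List::create(
      _["candidates"] = cands,
      _["unmappable"] = LogicalVector(idx.unmappable.begin(),
                                      idx.unmappable.end()));
}
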