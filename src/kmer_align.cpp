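#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <string>

using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (notably N) is -1 and breaks k-mers.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char code_base(int c) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[c & 3];
}

// Rolling k-mer codes over a sequence; positions with any non-ACGT base get
// code UINT64_MAX (sentinel). k <= 31 so the code fits 62 bits.
static void kmer_codes(const std::string& s, int k,
                       std::vector<uint64_t>& out) {
  const uint64_t BAD = UINT64_MAX;
  size_t n = s.size();
  out.assign(n >= (size_t)k ? n - k + 1 : 0, BAD);
  if (out.empty()) return;
  uint64_t mask = (k == 32) ? UINT64_MAX : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;  // length of current clean run
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    ++run;
    if (run >= k) out[i - k + 1] = val;
  }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = code_base((int)(code & 3)); code >>= 2; }
  return s;
}

// ---------------------------------------------------------------------------
// Window aligner: dense exact k-mer index over the target, per-window anchor
// collection, diagonal-run chaining, and ungapped match counting on the
// chained diagonals.
// ---------------------------------------------------------------------------

struct Seed { uint64_t key; uint32_t sid; uint32_t pos; };

struct Run {           // maximal group of anchors on one diagonal
  int qs, qe;          // query span [qs, qe) in anchor start positions + k
  int64_t diag;        // tpos - qpos
  int bases;           // anchored query bases (union of [q, q+k) spans)
};

struct Chain {
  std::vector<int> runs;  // indices into run vector
  int score;              // anchored bases
};

struct HitOut {
  int win, sid; char strand;
  int qstart, qend, tstart, tend, matches, block_len;
};

// Align one window orientation against one target sequence given its anchors
// (qpos, tpos). Returns true and fills hit fields on success.
static bool chain_and_count(const std::string& wseq, const std::string& tseq,
                            std::vector<std::pair<int,int64_t> >& anchors,
                            int k, int band, int chain_gap, int min_anchor_bases,
                            int& qstart, int& qend, int& tstart, int& tend,
                            int& matches, int& block_len, int& anchored) {
  if (anchors.empty()) return false;
  // anchors: (qpos, diag). Group into runs per diagonal.
  std::sort(anchors.begin(), anchors.end(),
            [](const std::pair<int,int64_t>& a, const std::pair<int,int64_t>& b) {
              if (a.second != b.second) return a.second < b.second;
              return a.first < b.first;
            });
  std::vector<Run> runs;
  for (size_t i = 0; i < anchors.size(); ++i) {
    int q = anchors[i].first;
    int64_t d = anchors[i].second;
    if (!runs.empty() && runs.back().diag == d && q <= runs.back().qe + chain_gap) {
      Run& r = runs.back();
      r.bases += std::min(k, q + k - r.qe);
      r.qe = std::max(r.qe, q + k);
    } else {
      runs.push_back(Run{q, q + k, d, k});
    }
  }
  // Chain runs by DP: sorted by qs, require query progression, bounded
  // diagonal drift, bounded query gap.
  std::sort(runs.begin(), runs.end(),
            [](const Run& a, const Run& b) { return a.qs < b.qs; });
  int R = (int)runs.size();
  std::vector<int> dp(R), prev(R, -1);
  int best = -1, best_score = 0;
  for (int i = 0; i < R; ++i) {
    dp[i] = runs[i].bases;
    for (int j = 0; j < i; ++j) {
      if (runs[j].qe > runs[i].qs + k) continue;           // too much overlap
      if (runs[i].qs - runs[j].qe > chain_gap) continue;    // unanchored gap
      int64_t dd = runs[i].diag - runs[j].diag;
      if (dd > band || dd < -band) continue;                // diagonal drift
      if (dp[j] + runs[i].bases > dp[i]) {
        dp[i] = dp[j] + runs[i].bases;
        prev[i] = j;
      }
    }
    if (dp[i] > best_score) { best_score = dp[i]; best = i; }
  }
  if (best < 0 || best_score < min_anchor_bases) return false;
  anchored = best_score;
  std::vector<int> chain;
  for (int i = best; i >= 0; i = prev[i]) chain.push_back(i);
  std::reverse(chain.begin(), chain.end());

  // Segment the window: each q-range compared on the diagonal of its nearest
  // chained run (boundaries at midpoints); chain ends extend to the window
  // boundaries (ungapped extension), clipped at target bounds.
  int wlen = (int)wseq.size(), tlen = (int)tseq.size();
  int nseg = (int)chain.size();
  matches = 0;
  qstart = wlen; qend = 0; tstart = tlen; tend = 0;
  for (int s = 0; s < nseg; ++s) {
    const Run& r = runs[chain[s]];
    int qa = (s == 0) ? 0 : (runs[chain[s - 1]].qe + r.qs) / 2;
    int qb = (s == nseg - 1) ? wlen : (r.qe + runs[chain[s + 1]].qs) / 2;
    // clip to target bounds on this diagonal
    int64_t d = r.diag;
    int lo = qa, hi = qb;
    if ((int64_t)lo + d < 0) lo = (int)(-d);
    if ((int64_t)hi + d > tlen) hi = (int)(tlen - d);
    if (hi <= lo) continue;
    for (int q = lo; q < hi; ++q)
      if (wseq[q] == tseq[q + d]) ++matches;
    qstart = std::min(qstart, lo);
    qend = std::max(qend, hi);
    tstart = std::min(tstart, (int)(lo + d));
    tend = std::max(tend, (int)(hi + d));
  }
  if (qend <= qstart) return false;
  block_len = std::max(qend - qstart, tend - tstart);
  return true;
}

//' @noRd
// [[Rcpp::export]]
DataFrame cpp_align_windows(CharacterVector window_seqs,
                            CharacterVector target_seqs,
                            int k, int occ_cap, int max_hits,
                            int band, int chain_gap, int min_anchor_bases,
                            int stride) {
  int nt = target_seqs.size(), nw = window_seqs.size();
  std::vector<std::string> tseqs(nt);
  for (int t = 0; t < nt; ++t) tseqs[t] = as<std::string>(target_seqs[t]);

  // Build sorted dense seed index over all target sequences.
  std::vector<Seed> index;
  {
    size_t total = 0;
    for (int t = 0; t < nt; ++t)
      if (tseqs[t].size() >= (size_t)k) total += tseqs[t].size() - k + 1;
    index.reserve(total);
    std::vector<uint64_t> codes;
    for (int t = 0; t < nt; ++t) {
      kmer_codes(tseqs[t], k, codes);
      for (size_t p = 0; p < codes.size(); ++p)
        if (codes[p] != UINT64_MAX)
          index.push_back(Seed{codes[p], (uint32_t)t, (uint32_t)p});
    }
    std::sort(index.begin(), index.end(),
              [](const Seed& a, const Seed& b) { return a.key < b.key; });
  }
  auto lookup = [&](uint64_t key, std::vector<const Seed*>& out) {
    out.clear();
    Seed probe{key, 0, 0};
    auto lo = std::lower_bound(index.begin(), index.end(), probe,
      [](const Seed& a, const Seed& b) { return a.key < b.key; });
    auto hi = lo;
    while (hi != index.end() && hi->key == key) ++hi;
    if (hi - lo > occ_cap) return;  // repetitive seed, skip
    for (auto it = lo; it != hi; ++it) out.push_back(&*it);
  };

  std::vector<HitOut> hits;
  std::vector<uint64_t> wcodes;
  std::vector<const Seed*> found;

  for (int w = 0; w < nw; ++w) {
    std::string fwd = as<std::string>(window_seqs[w]);
    int wlen = (int)fwd.size();
    std::string rev(fwd.rbegin(), fwd.rend());
    for (auto& c : rev) {
      switch (c) { case 'A': c = 'T'; break; case 'T': c = 'A'; break;
                   case 'C': c = 'G'; break; case 'G': c = 'C'; break; }
    }
    // best hit per (target sid): keep max matches over both orientations;
    // the reverse orientation is skipped when the forward chains already
    // anchor most of the window (no inversion can beat them).
    std::unordered_map<int, HitOut> best;
    int fwd_best_anchor = 0;
    for (int ori = 0; ori < 2; ++ori) {
      if (ori == 1 && fwd_best_anchor >= wlen / 2) break;
      const std::string& wseq = (ori == 0) ? fwd : rev;
      kmer_codes(wseq, k, wcodes);
      // anchors grouped per target sequence
      std::unordered_map<int, std::vector<std::pair<int,int64_t> > > anch;
      for (size_t q = 0; q < wcodes.size(); q += stride) {
        if (wcodes[q] == UINT64_MAX) continue;
        lookup(wcodes[q], found);
        for (const Seed* s : found)
          anch[s->sid].push_back(std::make_pair((int)q, (int64_t)s->pos - (int64_t)q));
      }
      for (auto& kv : anch) {
        int qs, qe, ts, te, m, bl, anc = 0;
        if (!chain_and_count(wseq, tseqs[kv.first], kv.second, k, band,
                             chain_gap, min_anchor_bases, qs, qe, ts, te, m, bl,
                             anc))
          continue;
        if (ori == 0 && anc > fwd_best_anchor) fwd_best_anchor = anc;
        HitOut h;
        h.win = w + 1; h.sid = kv.first + 1;
        h.strand = (ori == 0) ? '+' : '-';
        if (ori == 1) { int a = qs; qs = wlen - qe; qe = wlen - a; }
        h.qstart = qs; h.qend = qe; h.tstart = ts; h.tend = te;
        h.matches = m; h.block_len = bl;
        auto it = best.find(kv.first);
        if (it == best.end() || m > it->second.matches) best[kv.first] = h;
      }
    }
    std::vector<HitOut> wh;
    for (auto& kv : best) wh.push_back(kv.second);
    std::sort(wh.begin(), wh.end(), [](const HitOut& a, const HitOut& b) {
      if (a.matches != b.matches) return a.matches > b.matches;
      return a.sid < b.sid;
    });
    int keep = std::min((int)wh.size(), max_hits);
    // keep ties with the last retained hit so downstream tie policy sees them
    while (keep < (int)wh.size() && wh[keep].matches == wh[keep - 1].matches) ++keep;
    for (int i = 0; i < keep; ++i) hits.push_back(wh[i]);
  }

  int n = (int)hits.size();
  IntegerVector win(n), sid(n), qstart(n), qend(n), tstart(n), tend(n),
      matches(n), block_len(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    win[i] = hits[i].win; sid[i] = hits[i].sid;
    strand[i] = std::string(1, hits[i].strand);
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    tstart[i] = hits[i].tstart; tend[i] = hits[i].tend;
    matches[i] = hits[i].matches; block_len[i] = hits[i].block_len;
  }
  return DataFrame::create(_["win"] = win, _["sid"] = sid,
                           _["strand"] = strand,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["tstart"] = tstart, _["tend"] = tend,
                           _["matches"] = matches, _["block_len"] = block_len,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Diagnostic k-mers: canonical k-mers occurring >= min_count times with start
// inside the region union and never starting outside it.
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_diag_kmers(CharacterVector seqs,
                               IntegerVector region_sid,
                               IntegerVector region_start,
                               IntegerVector region_end,
                               int k, int min_count) {
  int ns = seqs.size();
  std::vector<std::string> ss(ns);
  for (int i = 0; i < ns; ++i) ss[i] = as<std::string>(seqs[i]);
  // inside mask per sequence
  std::vector<std::vector<char> > inside(ns);
  for (int i = 0; i < ns; ++i) inside[i].assign(ss[i].size(), 0);
  for (int r = 0; r < region_sid.size(); ++r) {
    int sid = region_sid[r] - 1;
    int a = region_start[r], b = region_end[r];
    for (int p = a; p < b && p < (int)inside[sid].size(); ++p) inside[sid][p] = 1;
  }
  std::unordered_map<uint64_t, std::pair<uint32_t, uint32_t> > counts;
  std::vector<uint64_t> codes;
  for (int i = 0; i < ns; ++i) {
    kmer_codes(ss[i], k, codes);
    for (size_t p = 0; p < codes.size(); ++p) {
      if (codes[p] == UINT64_MAX) continue;
      uint64_t canon = std::min(codes[p], revcomp_code(codes[p], k));
      auto& c = counts[canon];
      if (inside[i][p]) c.first++; else c.second++;
    }
  }
  std::vector<std::string> out;
  for (auto& kv : counts)
    if (kv.second.first >= (uint32_t)min_count && kv.second.second == 0)
      out.push_back(decode_kmer(kv.first, k));
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Coverage mask of a k-mer set: bases covered by >= 1 occurrence span of any
// set member, matching canonically (both strands).
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export]]
List cpp_kmer_coverage(CharacterVector seqs, CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  std::vector<uint64_t> codes;
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    kmer_codes(km, k, codes);
    if (codes.size() == 1 && codes[0] != UINT64_MAX)
      set.insert(std::min(codes[0], revcomp_code(codes[0], k)));
  }
  int ns = seqs.size();
  List out(ns);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    LogicalVector mask(s.size(), false);
    kmer_codes(s, k, codes);
    int cover_until = -1;
    for (size_t p = 0; p < codes.size(); ++p) {
      if (codes[p] != UINT64_MAX &&
          set.count(std::min(codes[p], revcomp_code(codes[p], k))))
        cover_until = (int)p + k;
      if ((int)p < cover_until) mask[p] = true;
    }
    for (int p = std::max(0, (int)codes.size()); p < cover_until && p < (int)s.size(); ++p)
      mask[p] = true;
    out[i] = mask;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
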