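#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; anything outside ACGT (notably N) encodes as -1 and
// never matches, not even itself. Lowercase (soft-masked) folds to uppercase.
static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> enc_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t) enc_base(s[i]);
  return v;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'a': c = 't'; break;
    case 'C': c = 'G'; break; case 'c': c = 'g'; break;
    case 'G': c = 'C'; break; case 'g': c = 'c'; break;
    case 'T': c = 'A'; break; case 't': c = 'a'; break;
    default: break;
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Seeded, banded local alignment
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int>> KmerMap;

static void index_kmers(const std::vector<int8_t>& q, int k, KmerMap& map) {
  if ((int) q.size() < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t kmer = 0;
  int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    int b = q[i];
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++run >= k) map[kmer].push_back((int)(i - k + 1));
  }
}

struct Seed { int q, t; };

struct AlnHit {
  int qs, qe, ts, te;       // 0-based half-open on query / target
  int cols, matches, score;
  int strand;               // 0 = '+', 1 = '-'
  int chrom;
};

// Banded Smith-Waterman, linear gap cost, band on diagonal d = j - i in
// [dlo, dhi]. Returns the best local alignment within the band.
static bool banded_local(const std::vector<int8_t>& q, const std::vector<int8_t>& t,
                         int dlo, int dhi, int match, int mismatch, int gapcost,
                         AlnHit& out) {
  const int m = (int) q.size(), n = (int) t.size();
  const int W = dhi - dlo + 1;
  if (W <= 0 || m == 0 || n == 0) return false;
  std::vector<int> prev((size_t) W, 0), cur((size_t) W, 0);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0); // 0 stop, 1 diag, 2 up, 3 left
  int bscore = 0, bi = -1, bb = -1;
  for (int i = 1; i <= m; ++i) {
    for (int b = 0; b < W; ++b) {
      int j = i + dlo + b;           // target column (1-based)
      if (j < 1 || j > n) { cur[b] = 0; continue; }
      int sub = (q[i - 1] >= 0 && q[i - 1] == t[j - 1]) ? match : mismatch;
      int sc = prev[b] + sub;        // diagonal keeps the same band offset
      uint8_t dir = 1;
      if (b + 1 < W) {               // gap in target: (i-1, j) is offset b+1
        int v = prev[b + 1] - gapcost;
        if (v > sc) { sc = v; dir = 2; }
      }
      if (b - 1 >= 0) {              // gap in query: (i, j-1) is offset b-1
        int v = cur[b - 1] - gapcost;
        if (v > sc) { sc = v; dir = 3; }
      }
      if (sc <= 0) { sc = 0; dir = 0; }
      cur[b] = sc;
      tb[(size_t) i * W + b] = dir;
      if (sc > bscore) { bscore = sc; bi = i; bb = b; }
    }
    std::swap(prev, cur);
  }
  if (bscore <= 0) return false;
  int i = bi, b = bb, matches = 0, cols = 0;
  const int qe = bi, te = bi + dlo + bb;
  while (i > 0) {
    uint8_t dir = tb[(size_t) i * W + b];
    if (dir == 0) break;
    if (dir == 1) {
      int j = i + dlo + b;
      if (q[i - 1] >= 0 && q[i - 1] == t[j - 1]) ++matches;
      ++cols; --i;
    } else if (dir == 2) { ++cols; --i; ++b; }
    else { ++cols; --b; }
  }
  out.qs = i; out.qe = qe;
  out.ts = i + dlo + b; out.te = te;
  out.cols = cols; out.matches = matches; out.score = bscore;
  return true;
}

// Gapless X-drop extension of a single seed along its diagonal. Returns the
// best-scoring segment (match +1 / mismatch -1) through the seed; used to
// discard spurious single-seed chains before the banded DP.
static void xdrop_segment(const std::vector<int8_t>& q, const std::vector<int8_t>& t,
                          int qpos, int tpos, int k, int xdrop,
                          int& cols, int& matches) {
  const int m = (int) q.size(), n = (int) t.size();
  cols = k; matches = k; // the seed itself is an exact run
  int sc = k, best = k, ext_cols = 0, ext_matches = 0;
  int bc = 0, bm = 0;
  for (int i = qpos + k, j = tpos + k; i < m && j < n; ++i, ++j) {
    bool mt = q[i] >= 0 && q[i] == t[j];
    sc += mt ? 1 : -1; ++ext_cols; if (mt) ++ext_matches;
    if (sc > best) { best = sc; bc = ext_cols; bm = ext_matches; }
    if (sc <= best - xdrop) break;
  }
  cols += bc; matches += bm;
  sc = best; int best2 = best; ext_cols = 0; ext_matches = 0; bc = 0; bm = 0;
  for (int i = qpos - 1, j = tpos - 1; i >= 0 && j >= 0; --i, --j) {
    bool mt = q[i] >= 0 && q[i] == t[j];
    sc += mt ? 1 : -1; ++ext_cols; if (mt) ++ext_matches;
    if (sc > best2) { best2 = sc; bc = ext_cols; bm = ext_matches; }
    if (sc <= best2 - xdrop) break;
  }
  cols += bc; matches += bm;
}

// Align one oriented query against one target: exact k-mer seeds grouped into
// diagonal chains, one banded extension per chain.
static void align_one(const std::vector<int8_t>& q, const std::vector<int8_t>& t,
                      int k, int band_pad, int max_seed_gap, int diag_slack,
                      int match, int mismatch, int gapcost,
                      int min_len, double min_identity,
                      int strand, int chrom, std::vector<AlnHit>& hits) {
  const int m = (int) q.size(), n = (int) t.size();
  if (m < k || n < k) return;
  KmerMap qmap;
  index_kmers(q, k, qmap);
  if (qmap.empty()) return;
  std::vector<Seed> seeds;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t kmer = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = t[i];
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) b) & mask;
    if (++run >= k) {
      auto it = qmap.find(kmer);
      if (it != qmap.end()) {
        int tpos = i - k + 1;
        for (int qpos : it->second) seeds.push_back({qpos, tpos});
      }
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    int da = a.t - a.q, db = b.t - b.q;
    if (da != db) return da < db;
    return a.t < b.t;
  });
  size_t i0 = 0;
  while (i0 < seeds.size()) {
    size_t i1 = i0 + 1;
    int dmin = seeds[i0].t - seeds[i0].q, dmax = dmin;
    int tlast = seeds[i0].t;
    while (i1 < seeds.size()) {
      int d = seeds[i1].t - seeds[i1].q;
      if (d - dmax > diag_slack) break;
      if (d == dmax && seeds[i1].t - tlast > max_seed_gap) break;
      if (d > dmax) { dmax = d; }
      tlast = seeds[i1].t;
      ++i1;
    }
    if (i1 - i0 == 1) {
      // Single-seed chain: a genuine alignment region almost always seeds
      // repeatedly, while random k-mer matches rarely extend. Require a
      // gapless X-drop segment of >= 2k columns at the identity threshold
      // before paying for the banded DP.
      int cols, matches;
      xdrop_segment(q, t, seeds[i0].q, seeds[i0].t, k, 8, cols, matches);
      if (cols < 2 * k || (double) matches / cols < min_identity - 1e-12) {
        i0 = i1;
        continue;
      }
    }
    AlnHit h;
    if (banded_local(q, t, dmin - band_pad, dmax + band_pad,
                     match, mismatch, gapcost, h)) {
      double ident = h.cols > 0 ? (double) h.matches / h.cols : 0.0;
      if (h.cols >= min_len && ident >= min_identity - 1e-12) {
        h.strand = strand; h.chrom = chrom;
        hits.push_back(h);
      }
    }
    i0 = i1;
  }
}

// Drop redundant hits: on the same target and strand, if two hits' target
// intervals overlap by >= 90% of the shorter one, keep the higher-scoring
// (ties: more matches, then leftmost target, then leftmost query).
static std::vector<AlnHit> dedupe_hits(std::vector<AlnHit> hits) {
  std::vector<size_t> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (hits[a].score != hits[b].score) return hits[a].score > hits[b].score;
    if (hits[a].matches != hits[b].matches) return hits[a].matches > hits[b].matches;
    if (hits[a].ts != hits[b].ts) return hits[a].ts < hits[b].ts;
    return hits[a].qs < hits[b].qs;
  });
  std::vector<AlnHit> kept;
  for (size_t idx : ord) {
    const AlnHit& h = hits[idx];
    bool redundant = false;
    for (const AlnHit& g : kept) {
      if (g.chrom != h.chrom || g.strand != h.strand) continue;
      int ov = std::min(g.te, h.te) - std::max(g.ts, h.ts);
      if (ov <= 0) continue;
      int shorter = std::min(g.te - g.ts, h.te - h.ts);
      if (shorter > 0 && (double) ov / shorter >= 0.9) { redundant = true; break; }
    }
    if (!redundant) kept.push_back(h);
  }
  return kept;
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, CharacterVector targets,
                          int min_len, double min_identity,
                          int kmer, int band_pad, int max_seed_gap, int diag_slack,
                          int match, int mismatch, int gapcost) {
  const int m = (int) query.size();
  std::vector<int8_t> qf = enc_seq(query);
  std::vector<int8_t> qr = enc_seq(cpp_revcomp(query));
  std::vector<AlnHit> hits;
  for (int c = 0; c < targets.size(); ++c) {
    std::string tseq = as<std::string>(targets[c]);
    std::vector<int8_t> t = enc_seq(tseq);
    align_one(qf, t, kmer, band_pad, max_seed_gap, diag_slack,
              match, mismatch, gapcost, min_len, min_identity, 0, c, hits);
    align_one(qr, t, kmer, band_pad, max_seed_gap, diag_slack,
              match, mismatch, gapcost, min_len, min_identity, 1, c, hits);
  }
  hits = dedupe_hits(hits);
  const size_t nh = hits.size();
  IntegerVector chrom(nh), ts(nh), te(nh), qs(nh), qe(nh), cols(nh),
    matches(nh), score(nh);
  CharacterVector strand(nh);
  for (size_t i = 0; i < nh; ++i) {
    const AlnHit& h = hits[i];
    chrom[i] = h.chrom + 1;
    ts[i] = h.ts; te[i] = h.te;
    if (h.strand == 0) { qs[i] = h.qs; qe[i] = h.qe; }
    else { qs[i] = m - h.qe; qe[i] = m - h.qs; } // map back to forward query
    cols[i] = h.cols; matches[i] = h.matches; score[i] = h.score;
    strand[i] = h.strand == 0 ? "+" : "-";
  }
  return DataFrame::create(
    Named("chrom_idx") = chrom, Named("t_start") = ts, Named("t_end") = te,
    Named("strand") = strand, Named("q_start") = qs, Named("q_end") = qe,
    Named("cols") = cols, Named("matches") = matches, Named("score") = score,
    Named("stringsAsFactors") = false);
}

// ---------------------------------------------------------------------------
// Gapless full-length probe matching with a mismatch cap
// ---------------------------------------------------------------------------

struct GaplessMatch { int probe, chrom, pos, mm; int strand; };

static int count_mm(const std::vector<int8_t>& p, const std::vector<int8_t>& t,
                    int start, int cap) {
  int mm = 0;
  for (size_t i = 0; i < p.size(); ++i) {
    int8_t a = p[i], b = t[start + i];
    if (a < 0 || a != b) { if (++mm > cap) return mm; }
  }
  return mm;
}

// Every gapless match of a length-L probe with <= cap mismatches contains an
// exact run of >= floor(L/(cap+1)) columns (pigeonhole); when that run is at
// least k long, exact k-mer seeding finds every match. Shorter probes fall
// back to a naive scan.
// [[Rcpp::export]]
List cpp_count_gapless(CharacterVector probes, CharacterVector targets,
                       double mismatch_frac, int kmer) {
  const int np = probes.size(), nt = targets.size();
  std::vector<std::vector<int8_t>> pseq(2 * np); // fwd then rev per probe
  std::vector<int> caps(np), plen(np);
  bool any_seeded = false, any_naive = false;
  for (int p = 0; p < np; ++p) {
    std::string s = as<std::string>(probes[p]);
    plen[p] = (int) s.size();
    caps[p] = (int) std::floor(mismatch_frac * s.size() + 1e-9);
    pseq[2 * p] = enc_seq(s);
    pseq[2 * p + 1] = enc_seq(cpp_revcomp(s));
    if (plen[p] / (caps[p] + 1) >= kmer) any_seeded = true; else any_naive = true;
  }
  // seed table: kmer -> (probe-orientation index, offset in probe)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> seedmap;
  if (any_seeded) {
    const uint64_t mask = (1ULL << (2 * kmer)) - 1;
    for (int p = 0; p < np; ++p) {
      if (plen[p] / (caps[p] + 1) < kmer) continue;
      for (int o = 0; o < 2; ++o) {
        const std::vector<int8_t>& q = pseq[2 * p + o];
        uint64_t km = 0; int run = 0;
        for (size_t i = 0; i < q.size(); ++i) {
          int b = q[i];
          if (b < 0) { run = 0; km = 0; continue; }
          km = ((km << 2) | (uint64_t) b) & mask;
          if (++run >= kmer)
            seedmap[km].push_back({2 * p + o, (int)(i - kmer + 1)});
        }
      }
    }
  }
  std::vector<GaplessMatch> matches;
  for (int c = 0; c < nt; ++c) {
    std::string ts = as<std::string>(targets[c]);
    std::vector<int8_t> t = enc_seq(ts);
    const int n = (int) t.size();
    if (any_seeded && !seedmap.empty()) {
      std::unordered_set<uint64_t> seen; // (probe-orient, start) already verified
      const uint64_t mask = (1ULL << (2 * kmer)) - 1;
      uint64_t km = 0; int run = 0;
      for (int i = 0; i < n; ++i) {
        int b = t[i];
        if (b < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t) b) & mask;
        if (run + 1 < kmer) { ++run; continue; }
        ++run;
        auto it = seedmap.find(km);
        if (it == seedmap.end()) continue;
        int tpos = i - kmer + 1;
        for (auto& pr : it->second) {
          int po = pr.first, off = pr.second;
          int start = tpos - off;
          int p = po / 2;
          if (start < 0 || start + plen[p] > n) continue;
          uint64_t key = ((uint64_t) po << 40) | (uint64_t)(uint32_t) start;
          if (!seen.insert(key).second) continue;
          int mm = count_mm(pseq[po], t, start, caps[p]);
          if (mm <= caps[p])
            matches.push_back({p, c, start, mm, po % 2});
        }
      }
    }
    if (any_naive) {
      for (int p = 0; p < np; ++p) {
        if (plen[p] / (caps[p] + 1) >= kmer) continue;
        for (int o = 0; o < 2; ++o) {
          const std::vector<int8_t>& q = pseq[2 * p + o];
          for (int start = 0; start + plen[p] <= n; ++start) {
            int mm = count_mm(q, t, start, caps[p]);
            if (mm <= caps[p]) matches.push_back({p, c, start, mm, o});
          }
        }
      }
    }
  }
  // Collapse overlapping matches per probe: best score (fewest mismatches)
  // wins; ties go to the leftmost start, then to the '+' strand.
  List out(np);
  for (int p = 0; p < np; ++p) {
    std::vector<GaplessMatch> mp;
    for (auto& m : matches) if (m.probe == p) mp.push_back(m);
    std::sort(mp.begin(), mp.end(), [](const GaplessMatch& a, const GaplessMatch& b) {
      if (a.mm != b.mm) return a.mm < b.mm;
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.strand < b.strand;
    });
    std::vector<GaplessMatch> kept;
    for (auto& m : mp) {
      bool clash = false;
      for (auto& g : kept) {
        if (g.chrom == m.chrom && std::abs(g.pos - m.pos) < plen[p]) { clash = true; break; }
      }
      if (!clash) kept.push_back(m);
    }
    std::sort(kept.begin(), kept.end(), [](const GaplessMatch& a, const GaplessMatch& b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      return a.pos < b.pos;
    });
    const size_t nk = kept.size();
    IntegerVector chrom(nk), pos(nk), mm(nk);
    CharacterVector strand(nk);
    for (size_t i = 0; i < nk; ++i) {
      chrom[i] = kept[i].chrom + 1;
      pos[i] = kept[i].pos;
      mm[i] = kept[i].mm;
      strand[i] = kept[i].strand == 0 ? "+" : "-";
    }
    out[p] = DataFrame::create(Named("chrom_idx") = chrom, Named("start") = pos,
                               Named("strand") = strand, Named("mismatches") = mm,
                               Named("stringsAsFactors") = false);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Tandem-repeat detection by period agreement
// ---------------------------------------------------------------------------

struct TrCand { int start, end, period, matches, run_len; };

// [[Rcpp::export]]
DataFrame cpp_detect_tandem(std::string seq, int min_period, int max_period,
                            double min_copies, double min_identity,
                            int min_len) {
  std::vector<int8_t> s = enc_seq(seq);
  const int n = (int) s.size();
  std::vector<TrCand> cands;
  for (int p = min_period; p <= max_period && p < n; ++p) {
    // x_i = match(i, i+p) - min_identity; maximal positive-score segments of x
    // are candidate agreement runs.
    double cur = 0, best = 0;
    int start = 0, best_end = -1, best_matches = 0, cur_matches = 0;
    const int lim = n - p;
    for (int i = 0; i <= lim; ++i) {
      bool mt = (i < lim) && s[i] >= 0 && s[i] == s[i + p];
      double x = mt ? (1.0 - min_identity) : -min_identity;
      bool flush = (i == lim);
      if (!flush) {
        cur += x;
        if (mt) ++cur_matches;
        if (cur > best) { best = cur; best_end = i; best_matches = cur_matches; }
        if (cur <= 0) flush = true;
      }
      if (flush) {
        if (best > 0 && best_end >= start) {
          int run_len = best_end - start + 1;
          int alen = run_len + p;
          if (alen >= min_len &&
              alen >= (int) std::ceil(min_copies * p) &&
              (double) best_matches / run_len >= min_identity - 1e-12) {
            cands.push_back({start, best_end + p + 1, p, best_matches, run_len});
          }
        }
        cur = 0; best = 0; cur_matches = 0; best_matches = 0;
        start = i + 1; best_end = -1;
      }
    }
  }
  // Overlap resolution: the longest agreement run wins. Comparing runs
  // (array length minus one period) rather than spans keeps a fundamental
  // period ahead of its harmonics, whose spans tie within end wobble.
  std::sort(cands.begin(), cands.end(), [](const TrCand& a, const TrCand& b) {
    if (a.run_len != b.run_len) return a.run_len > b.run_len;
    if (a.period != b.period) return a.period < b.period;
    return a.start < b.start;
  });
  std::vector<TrCand> kept;
  for (auto& c : cands) {
    bool clash = false;
    for (auto& g : kept)
      if (std::min(g.end, c.end) > std::max(g.start, c.start)) { clash = true; break; }
    if (!clash) kept.push_back(c);
  }
  std::sort(kept.begin(), kept.end(), [](const TrCand& a, const TrCand& b) {
    return a.start < b.start;
  });
  const size_t nk = kept.size();
  IntegerVector st(nk), en(nk), per(nk);
  NumericVector cn(nk), ident(nk);
  CharacterVector cons(nk);
  const char* bases = "ACGT";
  for (size_t i = 0; i < nk; ++i) {
    const TrCand& c = kept[i];
    st[i] = c.start; en[i] = c.end; per[i] = c.period;
    cn[i] = (double)(c.end - c.start) / c.period;
    ident[i] = (double) c.matches / c.run_len;
    std::string con(c.period, 'N');
    for (int col = 0; col < c.period; ++col) {
      int cnt[4] = {0, 0, 0, 0};
      for (int pos = c.start + col; pos < c.end; pos += c.period) {
        int b = s[pos];
        if (b >= 0) ++cnt[b];
      }
      int bi = -1, bc = 0;
      for (int b = 0; b < 4; ++b) if (cnt[b] > bc) { bc = cnt[b]; bi = b; }
      if (bi >= 0) con[col] = bases[bi];
    }
    cons[i] = con;
  }
  return DataFrame::create(
    Named("start") = st, Named("end") = en, Named("period") = per,
    Named("copy_number") = cn, Named("consensus") = cons,
    Named("mean_adjacent_identity") = ident, Named("stringsAsFactors") = false);
}
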