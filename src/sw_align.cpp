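#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local alignment of short queries against a set of
// reference sequences.  Seeds are exact k-mer matches found through a
// hash index of the reference; each cluster of seeds defines a subject
// window in which a full affine-gap Smith-Waterman with traceback is run.
// Gap cost convention matches Biostrings::pairwiseAlignment: a gap run of
// length L costs gap_open + gap_extend * L.

namespace {

const int NBASE = 4;

inline int base2int(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct Seed { int rid; int spos; int qpos; };

struct Aln {
  int score = 0;
  int sstart = 0, send = 0;   // 0-based half-open, window-local subject
  int qstart = 0, qend = 0;   // 0-based half-open on (possibly rc) query
  std::string qaln, saln;
  bool ok = false;
};

// Full Smith-Waterman over query q vs subject s with traceback.
Aln smith_waterman(const std::string& q, const std::string& s,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)q.size(), m = (int)s.size();
  Aln out;
  if (n == 0 || m == 0) return out;
  const int NEG = -1000000000;
  // traceback codes per cell: 2 bits for H origin (0 stop, 1 diag, 2 left(E),
  // 3 up(F)) plus extension flags for the E and F states.  Full quadratic
  // matrices: instances are windowed and small.
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  {
    std::vector<int> Hm((size_t)(n + 1) * (m + 1), 0);
    std::vector<int> Em((size_t)(n + 1) * (m + 1), NEG);
    std::vector<int> Fm((size_t)(n + 1) * (m + 1), NEG);
    auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
    best = 0; bi = 0; bj = 0;
    for (int i = 1; i <= n; ++i) {
      const int qb = base2int(q[i - 1]);
      for (int j = 1; j <= m; ++j) {
        const int sb = base2int(s[j - 1]);
        int eo = Hm[idx(i, j - 1)] - gap_open - gap_extend;
        int ee = Em[idx(i, j - 1)] - gap_extend;
        int E2 = std::max(eo, ee);
        int fo = Hm[idx(i - 1, j)] - gap_open - gap_extend;
        int fe = Fm[idx(i - 1, j)] - gap_extend;
        int F2 = std::max(fo, fe);
        int sub = (qb >= 0 && sb >= 0 && qb == sb) ? match : -mismatch;
        if (qb < 0 || sb < 0) sub = -mismatch; // N treated as mismatch
        int diag = Hm[idx(i - 1, j - 1)] + sub;
        int h = std::max(0, std::max(diag, std::max(E2, F2)));
        Hm[idx(i, j)] = h;
        Em[idx(i, j)] = E2;
        Fm[idx(i, j)] = F2;
        uint8_t code = 0;
        if (h == 0) code = 0;
        else if (h == diag) code = 1;
        else if (h == E2) code = 2;
        else code = 3;
        // extension flags: bit2 -> E came from extension; bit3 -> F ext
        if (ee >= eo) code |= 4;
        if (fe >= fo) code |= 8;
        tb[idx(i, j)] = code;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best <= 0) return out;
    // traceback
    std::string qa, sa;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (i > 0 && j > 0) {
      uint8_t code = tb[idx(i, j)];
      if (state == 0) {
        int c = code & 3;
        if (c == 0) break;
        if (c == 1) {
          qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
          --i; --j;
        } else if (c == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        // gap in query aligned string: consume subject base
        qa.push_back('-'); sa.push_back(s[j - 1]);
        bool ext = (tb[idx(i, j)] & 4) != 0;
        --j;
        if (!ext) state = 0;
      } else {
        qa.push_back(q[i - 1]); sa.push_back('-');
        bool ext = (tb[idx(i, j)] & 8) != 0;
        --i;
        if (!ext) state = 0;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    out.score = best;
    out.qstart = i; out.qend = bi;
    out.sstart = j; out.send = bj;
    out.qaln = qa; out.saln = sa;
    out.ok = true;
  }
  return out;
}

struct Hit {
  std::string qname, sname;
  char strand;
  int score;
  int qstart, qend;   // 1-based closed, original read orientation
  int sstart, send;   // 1-based closed, forward subject
  std::string qaln, saln;
};

// Split an alignment at gap runs longer than max_gap, keeping for each
// piece its maximal-scoring contiguous stretch of columns.
void emit_pieces(const Aln& a, int qoff_rcaware_start, int soff,
                 const std::string& qname, const std::string& sname,
                 char strand, int qlen,
                 int match, int mismatch, int gap_open, int gap_extend,
                 int max_gap, std::vector<Hit>& hits) {
  const std::string& qa = a.qaln;
  const std::string& sa = a.saln;
  const int L = (int)qa.size();
  // column scores (affine: open charged at first column of a gap run)
  std::vector<int> colscore(L);
  for (int t = 0; t < L; ++t) {
    if (qa[t] == '-' ) {
      bool first = (t == 0) || (qa[t - 1] != '-');
      colscore[t] = -(gap_extend + (first ? gap_open : 0));
    } else if (sa[t] == '-') {
      bool first = (t == 0) || (sa[t - 1] != '-');
      colscore[t] = -(gap_extend + (first ? gap_open : 0));
    } else {
      int qb = base2int(qa[t]), sb = base2int(sa[t]);
      colscore[t] = (qb >= 0 && qb == sb) ? match : -mismatch;
    }
  }
  // piece boundaries: break inside any gap run longer than max_gap
  std::vector<std::pair<int,int>> pieces;
  int start = 0, t = 0;
  while (t < L) {
    if (qa[t] == '-' || sa[t] == '-') {
      char g = qa[t] == '-' ? 'q' : 's';
      int rs = t;
      while (t < L && ((g == 'q' && qa[t] == '-') || (g == 's' && sa[t] == '-'))) ++t;
      if (t - rs > max_gap) {
        if (rs > start) pieces.push_back({start, rs});
        start = t;
      }
    } else ++t;
  }
  if (L > start) pieces.push_back({start, L});

  for (auto& pc : pieces) {
    // Kadane over columns for best contiguous sub-stretch
    int bestsum = 0, bs = -1, be = -1, cur = 0, cs = pc.first;
    for (int u = pc.first; u < pc.second; ++u) {
      cur += colscore[u];
      if (cur > bestsum) { bestsum = cur; bs = cs; be = u + 1; }
      if (cur < 0) { cur = 0; cs = u + 1; }
    }
    if (bs < 0 || bestsum <= 0) continue;
    // recompute coordinates for columns [bs, be)
    int qpos = a.qstart, spos = a.sstart; // 0-based on (rc)query/window
    for (int u = 0; u < bs; ++u) {
      if (qa[u] != '-') ++qpos;
      if (sa[u] != '-') ++spos;
    }
    int q0 = qpos, s0 = spos;
    for (int u = bs; u < be; ++u) {
      if (qa[u] != '-') ++qpos;
      if (sa[u] != '-') ++spos;
    }
    Hit h;
    h.qname = qname; h.sname = sname; h.strand = strand;
    h.score = bestsum;
    h.qaln = qa.substr(bs, be - bs);
    h.saln = sa.substr(bs, be - bs);
    h.sstart = soff + s0 + 1; h.send = soff + spos; // 1-based closed
    if (strand == '+') { h.qstart = q0 + 1; h.qend = qpos; }
    else { h.qstart = qlen - qpos + 1; h.qend = qlen - q0; }
    (void)qoff_rcaware_start;
    hits.push_back(h);
  }
}

} // namespace

// [[Rcpp::export(name = ".align_batch_cpp")]]
DataFrame align_batch_cpp(CharacterVector ref_names, CharacterVector ref_seqs,
                          CharacterVector q_names, CharacterVector q_seqs,
                          int k, int match, int mismatch,
                          int gap_open, int gap_extend, int max_gap,
                          int min_score, int max_windows, int min_seeds) {
  const int R = ref_seqs.size();
  std::vector<std::string> refs(R), rnames(R);
  for (int r = 0; r < R; ++r) {
    refs[r] = as<std::string>(ref_seqs[r]);
    rnames[r] = as<std::string>(ref_names[r]);
  }
  // k-mer index
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  index.reserve(1 << 20);
  for (int r = 0; r < R; ++r) {
    const std::string& s = refs[r];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2int(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back({r, p - k + 1});
    }
  }

  std::vector<Hit> hits;
  const int Q = q_seqs.size();
  for (int qi = 0; qi < Q; ++qi) {
    std::string qf = as<std::string>(q_seqs[qi]);
    std::string qname = as<std::string>(q_names[qi]);
    int qlen = (int)qf.size();
    if (qlen < k) continue;
    for (int sidx = 0; sidx < 2; ++sidx) {
      char strand = sidx == 0 ? '+' : '-';
      std::string qs = sidx == 0 ? qf : revcomp(qf);
      // seeds
      std::vector<Seed> seeds;
      {
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < qlen; ++p) {
          int b = base2int(qs[p]);
          if (b < 0) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)b) & mask;
          if (++run >= k) {
            auto it = index.find(key);
            if (it != index.end())
              for (auto& pr : it->second)
                seeds.push_back({pr.first, pr.second, p - k + 1});
          }
        }
      }
      if (seeds.empty()) continue;
      // cluster seeds into windows per reference: sort by (rid, diag, spos)
      std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
        if (a.rid != b.rid) return a.rid < b.rid;
        int da = a.spos - a.qpos, db = b.spos - b.qpos;
        if (da != db) return da < db;
        return a.spos < b.spos;
      });
      struct Win { int rid, lo, hi, nseed; };
      std::vector<Win> wins;
      const int band = std::max(32, max_gap + 8);
      size_t i0 = 0;
      for (size_t i = 1; i <= seeds.size(); ++i) {
        bool brk = i == seeds.size();
        if (!brk) {
          const Seed& a = seeds[i - 1];
          const Seed& b = seeds[i];
          int da = a.spos - a.qpos, db = b.spos - b.qpos;
          brk = (b.rid != a.rid) || (db - da > band) ||
                (b.spos - a.spos > 2 * qlen);
        }
        if (brk) {
          int rid = seeds[i0].rid;
          int lo = INT32_MAX, hi = 0;
          for (size_t u = i0; u < i; ++u) {
            lo = std::min(lo, seeds[u].spos - seeds[u].qpos);
            hi = std::max(hi, seeds[u].spos + (qlen - seeds[u].qpos));
          }
          // BLAST-style two-hit qualification: the cluster must contain
          // two non-overlapping seed matches within a short subject span,
          // which suppresses the chance diagonal coincidences a single
          // k-mer hit produces in megabase-scale subjects
          bool qualified = min_seeds <= 1;
          if (!qualified && (int)(i - i0) >= min_seeds) {
            const int two_hit_span = 40;
            std::vector<int> sp;
            sp.reserve(i - i0);
            for (size_t u = i0; u < i; ++u) sp.push_back(seeds[u].spos);
            std::sort(sp.begin(), sp.end());
            for (size_t u = 0; u + 1 < sp.size() && !qualified; ++u)
              for (size_t v = u + 1;
                   v < sp.size() && sp[v] - sp[u] <= two_hit_span; ++v)
                if (sp[v] - sp[u] >= k) { qualified = true; break; }
          }
          if (qualified) {
            int pad = band + 16;
            Win w;
            w.rid = rid;
            w.lo = std::max(0, lo - pad);
            w.hi = std::min((int)refs[rid].size(), hi + pad);
            w.nseed = (int)(i - i0);
            wins.push_back(w);
          }
          i0 = i;
        }
      }
      // merge overlapping windows on the same reference
      std::sort(wins.begin(), wins.end(), [](const Win& a, const Win& b) {
        if (a.rid != b.rid) return a.rid < b.rid;
        return a.lo < b.lo;
      });
      std::vector<Win> merged;
      for (auto& w : wins) {
        if (!merged.empty() && merged.back().rid == w.rid &&
            w.lo <= merged.back().hi) {
          merged.back().hi = std::max(merged.back().hi, w.hi);
          merged.back().nseed += w.nseed;
        } else merged.push_back(w);
      }
      if ((int)merged.size() > max_windows) {
        std::sort(merged.begin(), merged.end(), [](const Win& a, const Win& b) {
          return a.nseed > b.nseed;
        });
        merged.resize(max_windows);
      }
      for (auto& w : merged) {
        std::string sub = refs[w.rid].substr(w.lo, w.hi - w.lo);
        Aln a = smith_waterman(qs, sub, match, mismatch, gap_open, gap_extend);
        if (!a.ok || a.score < min_score) continue;
        emit_pieces(a, 0, w.lo, qname, rnames[w.rid], strand, qlen,
                    match, mismatch, gap_open, gap_extend, max_gap, hits);
      }
    }
    Rcpp::checkUserInterrupt();
  }

  const int n = (int)hits.size();
  CharacterVector qn(n), sn(n), st(n), qa(n), sa(n);
  IntegerVector sc(n), qs1(n), qe1(n), ss1(n), se1(n);
  for (int i = 0; i < n; ++i) {
    qn[i] = hits[i].qname; sn[i] = hits[i].sname;
    st[i] = std::string(1, hits[i].strand);
    sc[i] = hits[i].score;
    qs1[i] = hits[i].qstart; qe1[i] = hits[i].qend;
    ss1[i] = hits[i].sstart; se1[i] = hits[i].send;
    qa[i] = hits[i].qaln; sa[i] = hits[i].saln;
  }
  return DataFrame::create(
    _["qseqid"] = qn, _["sseqid"] = sn, _["strand"] = st,
    _["score"] = sc,
    _["qstart"] = qs1, _["qend"] = qe1,
    _["sstart"] = ss1, _["send"] = se1,
    _["qaln"] = qa, _["saln"] = sa,
    _["stringsAsFactors"] = false);
}
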