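// Seeded local nucleotide alignment with affine gaps, banded X-drop
// extension, DUST-style low-complexity masking, and a full Smith-Waterman
// scorer used for E-value calibration.  Gap cost convention: a gap of
// length L costs gap_open + gap_extend * L (every gapped column pays the
// extension penalty; the first additionally pays the opening penalty).
#include <Rcpp.h>
#include <cstdint>
#include <limits>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

static const int NEG = std::numeric_limits<int>::min() / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;  // N or anything else: never matches, never seeds
  }
}

static inline int sub_score(char a, char b, int match, int mismatch) {
  int ca = base_code(a), cb = base_code(b);
  if (ca < 0 || cb < 0) return mismatch;  // N scores as mismatch
  return (ca == cb) ? match : mismatch;
}

// [[Rcpp::export]]
int cpp_sw_score(std::string q, std::string s, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int n = (int)q.size(), m = (int)s.size();
  const int gi = gap_open + gap_extend;
  std::vector<int> H(m + 1, 0);       // H[i-1][*] rolling into H[i][*]
  std::vector<int> Ecol(m + 1, NEG);  // vertical (gap in subject) per column
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = H[0];
    int rowE = NEG;  // horizontal gap within this row
    for (int j = 1; j <= m; ++j) {
      Ecol[j] = std::max(H[j] - gi, Ecol[j] - gap_extend);
      rowE = std::max(H[j - 1] - gi, rowE - gap_extend);
      int h = Hdiag + sub_score(q[i - 1], s[j - 1], match, mismatch);
      if (Ecol[j] > h) h = Ecol[j];
      if (rowE > h) h = rowE;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// DUST-style masking: per-window score = sum_t c_t (c_t - 1) / 2 over the
// window's triplet counts, normalised by the triplet count (w - 2);
// windows with score > threshold are merged into maximal intervals.
// Triplets containing ambiguous bases are not counted.
// [[Rcpp::export]]
DataFrame cpp_mask_dust(std::string seq, int window, double threshold) {
  const int n = (int)seq.size();
  std::vector<int> starts, ends;
  if (n >= window && window >= 3) {
    const int ntrip = window - 2;
    std::vector<int> counts(64, 0);
    std::vector<int> tri(n, -1);
    for (int i = 0; i + 2 < n; ++i) {
      int a = base_code(seq[i]), b = base_code(seq[i + 1]),
          c = base_code(seq[i + 2]);
      tri[i] = (a < 0 || b < 0 || c < 0) ? -1 : (a << 4) | (b << 2) | c;
    }
    long long raw = 0;  // sum c_t (c_t - 1) / 2, updated incrementally
    auto add = [&](int t) { if (t >= 0) { raw += counts[t]; counts[t]++; } };
    auto del = [&](int t) { if (t >= 0) { counts[t]--; raw -= counts[t]; } };
    for (int i = 0; i < ntrip; ++i) add(tri[i]);
    int cur_s = -1, cur_e = -1;
    for (int w0 = 0; w0 + window <= n; ++w0) {
      if (w0 > 0) { del(tri[w0 - 1]); add(tri[w0 + ntrip - 1]); }
      if ((double)raw / (double)ntrip > threshold) {
        int a = w0, b = w0 + window;
        if (cur_s >= 0 && a <= cur_e) cur_e = b;
        else {
          if (cur_s >= 0) { starts.push_back(cur_s); ends.push_back(cur_e); }
          cur_s = a; cur_e = b;
        }
      }
    }
    if (cur_s >= 0) { starts.push_back(cur_s); ends.push_back(cur_e); }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends);
}

// ---- banded X-drop extension ---------------------------------------------

struct ExtResult {
  int best = 0;
  int qlen = 0, slen = 0;  // extension lengths at the best-scoring cell
  std::string cigar;       // per-column ops, best cell back to the origin
  int matches = 0, cols = 0;
};

// Extend from position 0 of q and s (semi-global: the path is anchored at
// the origin, no zero clamp), banded around the starting diagonal.  Rows are
// abandoned when their maximum falls more than xdrop below the running best.
// Traceback bits: 0-1 = H direction (0 stop, 1 diag, 2 horiz, 3 vert),
// bit 2 = horizontal gap extends, bit 3 = vertical gap extends.
static ExtResult xdrop_extend(const std::string& q, const std::string& s,
                              int match, int mismatch, int gap_open,
                              int gap_extend, int band, int xdrop) {
  ExtResult res;
  const int n = (int)q.size(), m = (int)s.size();
  if (n == 0 || m == 0) return res;  // pure-gap extension never helps
  const int gi = gap_open + gap_extend;
  const int width = 2 * band + 1;
  auto K = [band](int i, int j) { return j - i + band; };
  std::vector<int> H(width, NEG), E(width, NEG), F(width, NEG);
  std::vector<int> Hn(width, NEG), En(width, NEG), Fn(width, NEG);
  std::vector<std::vector<uint8_t>> tb;
  tb.reserve(128);

  int best = 0, bi = 0, bj = 0;
  {  // row 0: origin plus horizontal gaps along the subject
    std::vector<uint8_t> row(width, 0);
    H[K(0, 0)] = 0;
    for (int j = 1; j <= std::min(m, band); ++j) {
      int k = K(0, j);
      E[k] = -(gap_open + gap_extend * j);
      H[k] = E[k];
      row[k] = (uint8_t)(2 | (j > 1 ? 4 : 0));
    }
    tb.push_back(std::move(row));
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    if (jlo > jhi) break;
    std::fill(Hn.begin(), Hn.end(), NEG);
    std::fill(En.begin(), En.end(), NEG);
    std::fill(Fn.begin(), Fn.end(), NEG);
    std::vector<uint8_t> row(width, 0);
    int rowmax = NEG;
    for (int j = jlo; j <= jhi; ++j) {
      int k = K(i, j);
      uint8_t t = 0;
      int e = NEG, f = NEG, h = NEG;
      if (j > jlo && Hn[k - 1] > NEG / 2) {  // horizontal from (i, j-1)
        int e_open = Hn[k - 1] - gi;
        int e_ext = (En[k - 1] > NEG / 2) ? En[k - 1] - gap_extend : NEG;
        e = std::max(e_open, e_ext);
        if (e_ext > e_open) t |= 4;
      } else if (j > jlo && En[k - 1] > NEG / 2) {
        e = En[k - 1] - gap_extend; t |= 4;
      }
      if (k + 1 < width) {  // vertical from (i-1, j)
        int f_open = (H[k + 1] > NEG / 2) ? H[k + 1] - gi : NEG;
        int f_ext = (F[k + 1] > NEG / 2) ? F[k + 1] - gap_extend : NEG;
        f = std::max(f_open, f_ext);
        if (f_ext > f_open) t |= 8;
      }
      if (j > 0 && H[k] > NEG / 2)  // diagonal from (i-1, j-1)
        h = H[k] + sub_score(q[i - 1], s[j - 1], match, mismatch);
      int hh = h; uint8_t dir = 1;
      if (e > hh) { hh = e; dir = 2; }
      if (f > hh) { hh = f; dir = 3; }
      if (hh <= NEG / 2) { row[k] = t; continue; }
      Hn[k] = hh; En[k] = e; Fn[k] = f;
      row[k] = (uint8_t)(t | dir);
      if (hh > rowmax) rowmax = hh;
      if (hh > best) { best = hh; bi = i; bj = j; }
    }
    tb.push_back(std::move(row));
    H.swap(Hn); E.swap(En); F.swap(Fn);
    if (rowmax < best - xdrop) break;
  }

  if (best <= 0) return res;
  res.best = best; res.qlen = bi; res.slen = bj;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = horizontal gap, 2 = vertical
  std::string ops;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i][K(i, j)];
    if (state == 0) {
      int dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        bool eq = base_code(q[i - 1]) >= 0 &&
                  base_code(q[i - 1]) == base_code(s[j - 1]);
        ops.push_back(eq ? '=' : 'X');
        --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('I');  // column present in subject only
      state = (t & 4) ? 1 : 0;
      --j;
    } else {
      ops.push_back('D');  // column present in query only
      state = (t & 8) ? 2 : 0;
      --i;
    }
  }
  res.cols = (int)ops.size();
  for (char c : ops) if (c == '=') res.matches++;
  res.cigar = ops;
  return res;
}

struct Hsp {
  int q0, q1, s0, s1;  // half-open intervals
  int score, matches, cols;
  std::string cigar;
};

// collapse '='/'X' to M and run-length encode; I = gap in query (subject
// base consumed), D = gap in subject (query base consumed) -- query-centric
static std::string rle(const std::string& cols) {
  std::string out;
  size_t i = 0;
  while (i < cols.size()) {
    char op = (cols[i] == '=' || cols[i] == 'X') ? 'M' : cols[i];
    size_t j = i;
    while (j < cols.size()) {
      char oj = (cols[j] == '=' || cols[j] == 'X') ? 'M' : cols[j];
      if (oj != op) break;
      ++j;
    }
    out += std::to_string(j - i);
    out.push_back(op);
    i = j;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string q, std::string s, int match,
                          int mismatch, int gap_open, int gap_extend,
                          int word, int band, int xdrop,
                          IntegerVector q_mask, IntegerVector s_mask,
                          int min_diag) {
  const int n = (int)q.size(), m = (int)s.size();
  std::vector<Hsp> hsps;
  if (m >= word && n >= word) {
    std::vector<char> qm(n, 0), sm(m, 0);
    for (int i = 0; i < q_mask.size(); ++i)
      if (q_mask[i] >= 0 && q_mask[i] < n) qm[q_mask[i]] = 1;
    for (int i = 0; i < s_mask.size(); ++i)
      if (s_mask[i] >= 0 && s_mask[i] < m) sm[s_mask[i]] = 1;

    // hash subject words; masked or ambiguous positions never seed
    std::unordered_map<uint64_t, std::vector<int>> idx;
    const uint64_t wmask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    uint64_t code = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      int c = base_code(s[j]);
      if (c < 0 || sm[j]) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & wmask;
      if (++run >= word) idx[code].push_back(j - word + 1);
    }
    std::vector<std::pair<int, int>> seeds;  // (q_start, s_start)
    code = 0; run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(q[i]);
      if (c < 0 || qm[i]) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & wmask;
      if (++run >= word) {
        auto it = idx.find(code);
        if (it != idx.end())
          for (int ss : it->second) seeds.emplace_back(i - word + 1, ss);
      }
    }
    std::sort(seeds.begin(), seeds.end(),
              [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
                int da = a.first - a.second, db = b.first - b.second;
                if (da != db) return da < db;
                return a.first < b.first;
              });

    // collapse seed runs: consecutive seeds on one diagonal describe the
    // same exact-match run, so only the run's first seed is extended
    std::unordered_set<long long> seen_run;
    auto run_key = [m](int qi, int si) {
      return (long long)qi * (long long)(m + 1) + si;
    };
    for (auto& sd : seeds) {
      int qs = sd.first, ss = sd.second, d = qs - ss;
      if (min_diag > 0 && std::abs(d) < min_diag) continue;
      if (seen_run.count(run_key(qs, ss))) {
        seen_run.insert(run_key(qs + 1, ss + 1));
        continue;
      }
      seen_run.insert(run_key(qs + 1, ss + 1));
      std::string qf = q.substr((size_t)qs + word), sf = s.substr((size_t)ss + word);
      std::string qb = q.substr(0, (size_t)qs), sb = s.substr(0, (size_t)ss);
      std::reverse(qb.begin(), qb.end());
      std::reverse(sb.begin(), sb.end());
      ExtResult fw = xdrop_extend(qf, sf, match, mismatch, gap_open,
                                  gap_extend, band, xdrop);
      ExtResult bw = xdrop_extend(qb, sb, match, mismatch, gap_open,
                                  gap_extend, band, xdrop);
      Hsp h;
      h.q0 = qs - bw.qlen; h.q1 = qs + word + fw.qlen;
      h.s0 = ss - bw.slen; h.s1 = ss + word + fw.slen;
      h.score = fw.best + bw.best + word * match;
      h.matches = fw.matches + bw.matches + word;
      h.cols = fw.cols + bw.cols + word;
      // bw.cigar reads left-to-right already (reversed extension of reversed
      // strings); fw.cigar must be reversed to read left-to-right
      std::string fwd = fw.cigar;
      std::reverse(fwd.begin(), fwd.end());
      std::string cols = bw.cigar + std::string((size_t)word, '=') + fwd;
      h.cigar = rle(cols);
      hsps.push_back(std::move(h));
    }
    // keep the maximum-score representative among overlapping HSPs
    std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.q0 != b.q0) return a.q0 < b.q0;
      return a.s0 < b.s0;
    });
    std::vector<Hsp> kept;
    for (auto& h : hsps) {
      bool drop = false;
      for (auto& k : kept) {
        int qo = std::min(h.q1, k.q1) - std::max(h.q0, k.q0);
        int so = std::min(h.s1, k.s1) - std::max(h.s0, k.s0);
        if (qo > 0 && so > 0) { drop = true; break; }
      }
      if (!drop) kept.push_back(h);
    }
    hsps.swap(kept);
  }

  int nh = (int)hsps.size();
  IntegerVector q0(nh), q1(nh), s0(nh), s1(nh), sc(nh), mt(nh), cl(nh);
  CharacterVector cg(nh);
  for (int i = 0; i < nh; ++i) {
    q0[i] = hsps[i].q0; q1[i] = hsps[i].q1;
    s0[i] = hsps[i].s0; s1[i] = hsps[i].s1;
    sc[i] = hsps[i].score; mt[i] = hsps[i].matches; cl[i] = hsps[i].cols;
    cg[i] = hsps[i].cigar;
  }
  return DataFrame::create(_["q_start"] = q0, _["q_end"] = q1,
                           _["s_start"] = s0, _["s_end"] = s1,
                           _["score"] = sc, _["matches"] = mt,
                           _["aligned_columns"] = cl, _["cigar"] = cg,
                           _["stringsAsFactors"] = false);
}
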